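#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Banded global alignment under unit costs (mismatch 1, indel 1), i.e. a
// Levenshtein-optimal alignment, with a traceback that reports column
// composition. The band is doubled until the optimal cost is provably inside
// it (Ukkonen-style), so the result is exact.
//
// Returns c(columns, matches, mismatches, gap_columns).

static bool band_align(const std::string &a, const std::string &b, int band,
                       std::vector<int> &out) {
  const int la = (int)a.size(), lb = (int)b.size();
  const int W = 2 * band + 1;
  const int INF = 1 << 28;
  // dp[i][d] = cost aligning a[0..i) with b[0..j) where j = i + d - band
  std::vector<int> dp((size_t)(la + 1) * W, INF);
  std::vector<uint8_t> bt((size_t)(la + 1) * W, 0); // 1 diag, 2 up(del b gap), 3 left(ins)
  for (int d = band; d < W; ++d) {
    int j = d - band;
    if (j > lb) break;
    dp[d] = j; // first row: j insertions
    bt[d] = 3;
  }
  for (int i = 1; i <= la; ++i) {
    for (int d = 0; d < W; ++d) {
      int j = i + d - band;
      if (j < 0 || j > lb) continue;
      int best = INF;
      uint8_t dir = 0;
      if (j == 0) {
        best = i; dir = 2;
      } else {
        // diagonal: same d in row i-1
        int c = dp[(size_t)(i - 1) * W + d];
        if (c < INF) {
          c += (a[i - 1] == b[j - 1]) ? 0 : 1;
          if (c < best) { best = c; dir = 1; }
        }
        // up (consume a, gap in b): row i-1, d+1
        if (d + 1 < W) {
          int cu = dp[(size_t)(i - 1) * W + d + 1];
          if (cu < INF && cu + 1 < best) { best = cu + 1; dir = 2; }
        }
        // left (consume b, gap in a): same row, d-1
        if (d - 1 >= 0) {
          int cl = dp[(size_t)i * W + d - 1];
          if (cl < INF && cl + 1 < best) { best = cl + 1; dir = 3; }
        }
      }
      dp[(size_t)i * W + d] = best;
      bt[(size_t)i * W + d] = dir;
    }
  }
  int dEnd = lb - la + band;
  if (dEnd < 0 || dEnd >= W) return false;
  int cost = dp[(size_t)la * W + dEnd];
  if (cost >= (1 << 28)) return false;
  // cost >= band means a cheaper path outside the band could exist
  if (cost >= band && band < std::max(la, lb) + 1) return false;

  int cols = 0, match = 0, mm = 0, gap = 0;
  int i = la, d = dEnd;
  while (i > 0 || (i + d - band) > 0) {
    uint8_t dir = bt[(size_t)i * W + d];
    int j = i + d - band;
    if (dir == 1) {
      ++cols;
      if (a[i - 1] == b[j - 1]) ++match; else ++mm;
      --i;
    } else if (dir == 2) {
      ++cols; ++gap; --i; ++d;
    } else if (dir == 3) {
      ++cols; ++gap; --d;
    } else {
      break;
    }
  }
  out[0] = cols; out[1] = match; out[2] = mm; out[3] = gap;
  return true;
}

// [[Rcpp::export]]
IntegerVector align_counts_cpp(std::string a, std::string b) {
  if (a.empty() || b.empty()) stop("empty sequence");
  int la = (int)a.size(), lb = (int)b.size();
  int band = std::abs(la - lb) + 16;
  std::vector<int> out(4, 0);
  while (true) {
    if (band > std::max(la, lb)) band = std::max(la, lb) + 1;
    if (band_align(a, b, band, out)) break;
    if (band > std::max(la, lb)) stop("alignment failed"); // unreachable
    band *= 2;
  }
  return IntegerVector::create(_["columns"] = out[0], _["matches"] = out[1],
                               _["mismatches"] = out[2], _["gaps"] = out[3]);
}
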