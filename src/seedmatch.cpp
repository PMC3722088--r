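#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// 2-bit DNA encoding; anything outside ACGT (notably N) maps to -1 and can
// never take part in a seed match.
static inline int8_t enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::vector<int8_t> encode(const std::string &s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc(s[i]);
  return v;
}

// packed codes for every k-mer start; valid[i] == false when the k-mer
// contains a non-ACGT character
static void kmer_codes(const std::vector<int8_t> &s, int k,
                       std::vector<uint64_t> &code, std::vector<char> &valid) {
  long n = (long)s.size() - k + 1;
  if (n < 0) n = 0;
  code.assign(n, 0);
  valid.assign(n, 0);
  if (n == 0) return;
  uint64_t c = 0;
  int bad = 0; // count of invalid chars in current k-window
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (long i = 0; i < (long)s.size(); ++i) {
    c = ((c << 2) | (uint64_t)(s[i] < 0 ? 0 : s[i])) & mask;
    if (s[i] < 0) bad = k; else if (bad > 0) --bad;
    long start = i - k + 1;
    if (start >= 0) {
      code[start] = c;
      valid[start] = (bad == 0);
    }
  }
}

// Hamming verification of a seed pair; rejects any seed touching a non-ACGT
// character. Returns true when mismatches <= max_mm.
static inline bool verify(const std::vector<int8_t> &a, long p,
                          const std::vector<int8_t> &b, long q,
                          int seed_len, int max_mm) {
  int mm = 0;
  for (int t = 0; t < seed_len; ++t) {
    int8_t x = a[p + t], y = b[q + t];
    if (x < 0 || y < 0) return false;
    if (x != y && ++mm > max_mm) return false;
  }
  return true;
}

// Count offset pairs (p, q) with Hamming(a[p..p+L), b[q..q+L)) <= max_mm,
// via the pigeonhole split of the seed into (max_mm + 1) exact parts.
// Exact count up to `cap` (cap <= 0 means unbounded).
// [[Rcpp::export]]
int count_seed_matches_cpp(std::string a, std::string b, int seed_len,
                           int max_mm, int cap) {
  std::vector<int8_t> ea = encode(a), eb = encode(b);
  long la = (long)ea.size(), lb = (long)eb.size();
  if (la < seed_len || lb < seed_len)
    stop("windows shorter than seed length");
  int npart = max_mm + 1;
  int lp = seed_len / npart;
  std::vector<uint64_t> ca, cb;
  std::vector<char> va, vb;
  kmer_codes(ea, lp, ca, va);
  kmer_codes(eb, lp, cb, vb);

  std::unordered_map<uint64_t, std::vector<long> > idx;
  for (long q = 0; q < (long)cb.size(); ++q)
    if (vb[q]) idx[cb[q]].push_back(q);

  long pmax = la - seed_len, qmax = lb - seed_len;
  int count = 0;
  for (long p = 0; p <= pmax; ++p) {
    for (int k = 0; k < npart; ++k) {
      long xp = p + (long)k * lp;
      if (!va[xp]) continue;
      std::unordered_map<uint64_t, std::vector<long> >::const_iterator it =
          idx.find(ca[xp]);
      if (it == idx.end()) continue;
      const std::vector<long> &hits = it->second;
      for (size_t h = 0; h < hits.size(); ++h) {
        long q = hits[h] - (long)k * lp;
        if (q < 0 || q > qmax) continue;
        // dedup: skip when an earlier part also matches exactly
        bool dup = false;
        for (int k2 = 0; k2 < k; ++k2) {
          long p2 = p + (long)k2 * lp, q2 = q + (long)k2 * lp;
          if (va[p2] && vb[q2] && ca[p2] == cb[q2]) { dup = true; break; }
        }
        if (dup) continue;
        if (verify(ea, p, eb, q, seed_len, max_mm)) {
          ++count;
          if (cap > 0 && count >= cap) return count;
        }
      }
    }
  }
  return count;
}

struct PairCount {
  std::unordered_map<uint64_t, int> m;
  int add(uint64_t key, int cap) {
    int &c = m[key];
    if (cap > 0 && c >= cap) return c;
    return ++c;
  }
  int get(uint64_t key) const {
    std::unordered_map<uint64_t, int>::const_iterator it = m.find(key);
    return it == m.end() ? 0 : it->second;
  }
};

// Self-comparative dot matrix over non-overlapping windows.
// Returns window-pair dots (0-based indices) for the upper triangle only;
// the R wrapper mirrors them. Orientation '+' compares forward windows,
// '-' compares a forward window against the reverse complement of another.
// [[Rcpp::export]]
List self_dotplot_cpp(std::string seq, int window_bp, int seed_len, int max_mm,
                      int min_hits, int min_offset_bp, bool search_reverse) {
  std::vector<int8_t> s = encode(seq);
  long n = (long)s.size() / window_bp;
  long tiled = n * window_bp;
  s.resize(tiled);

  int npart = max_mm + 1;
  int lp = seed_len / npart;
  int in_win = window_bp - seed_len; // max in-window seed offset

  std::vector<uint64_t> cf;
  std::vector<char> vf;
  kmer_codes(s, lp, cf, vf);
  std::unordered_map<uint64_t, std::vector<long> > idx;
  for (long x = 0; x < (long)cf.size(); ++x)
    if (vf[x]) idx[cf[x]].push_back(x);

  PairCount fwd;
  // forward: unordered position pairs x < y give i <= j directly
  for (std::unordered_map<uint64_t, std::vector<long> >::const_iterator it =
           idx.begin(); it != idx.end(); ++it) {
    const std::vector<long> &pos = it->second;
    for (size_t u = 0; u + 1 < pos.size(); ++u) {
      for (size_t v = u + 1; v < pos.size(); ++v) {
        long x = pos[u], y = pos[v];
        for (int k = 0; k < npart; ++k) {
          long p = x - (long)k * lp, q = y - (long)k * lp;
          if (p < 0 || q < 0) continue;
          long i = p / window_bp, j = q / window_bp;
          if (i == j) continue;
          if ((j - i) * (long)window_bp < min_offset_bp) continue;
          if (p - i * window_bp > in_win || q - j * window_bp > in_win)
            continue;
          uint64_t key = (uint64_t)i * (uint64_t)n + (uint64_t)j;
          if (min_hits > 0 && fwd.get(key) >= min_hits) continue;
          bool dup = false;
          for (int k2 = 0; k2 < k; ++k2) {
            long p2 = p + (long)k2 * lp, q2 = q + (long)k2 * lp;
            if (vf[p2] && vf[q2] && cf[p2] == cf[q2]) { dup = true; break; }
          }
          if (dup) continue;
          if (verify(s, p, s, q, seed_len, max_mm)) fwd.add(key, min_hits);
        }
      }
    }
  }

  PairCount rev;
  if (search_reverse && tiled > 0) {
    // reverse complement of the tiled sequence; rc-window jr maps back to
    // forward window n - 1 - jr
    std::vector<int8_t> r(tiled);
    for (long t = 0; t < tiled; ++t) {
      int8_t c = s[tiled - 1 - t];
      r[t] = (c < 0) ? -1 : (int8_t)(3 - c);
    }
    std::vector<uint64_t> cr;
    std::vector<char> vr;
    kmer_codes(r, lp, cr, vr);
    std::unordered_map<uint64_t, std::vector<long> > ridx;
    for (long y = 0; y < (long)cr.size(); ++y)
      if (vr[y]) ridx[cr[y]].push_back(y);

    for (std::unordered_map<uint64_t, std::vector<long> >::const_iterator it =
             idx.begin(); it != idx.end(); ++it) {
      std::unordered_map<uint64_t, std::vector<long> >::const_iterator jt =
          ridx.find(it->first);
      if (jt == ridx.end()) continue;
      const std::vector<long> &fp = it->second;
      const std::vector<long> &rp = jt->second;
      for (size_t u = 0; u < fp.size(); ++u) {
        for (size_t v = 0; v < rp.size(); ++v) {
          long x = fp[u], y = rp[v];
          for (int k = 0; k < npart; ++k) {
            long p = x - (long)k * lp, q = y - (long)k * lp;
            if (p < 0 || q < 0) continue;
            long i = p / window_bp, jr = q / window_bp;
            long j = n - 1 - jr;
            if (i >= j) continue; // lower triangle mirrored by symmetry
            if ((j - i) * (long)window_bp < min_offset_bp) continue;
            if (p - i * window_bp > in_win || q - jr * window_bp > in_win)
              continue;
            uint64_t key = (uint64_t)i * (uint64_t)n + (uint64_t)j;
            if (min_hits > 0 && rev.get(key) >= min_hits) continue;
            bool dup = false;
            for (int k2 = 0; k2 < k; ++k2) {
              long p2 = p + (long)k2 * lp, q2 = q + (long)k2 * lp;
              if (vf[p2] && vr[q2] && cf[p2] == cr[q2]) { dup = true; break; }
            }
            if (dup) continue;
            if (verify(s, p, r, q, seed_len, max_mm)) rev.add(key, min_hits);
          }
        }
      }
    }
  }

  std::vector<int> oi, oj;
  std::vector<std::string> ori;
  for (std::unordered_map<uint64_t, int>::const_iterator it = fwd.m.begin();
       it != fwd.m.end(); ++it) {
    if (it->second >= min_hits) {
      oi.push_back((int)(it->first / (uint64_t)n));
      oj.push_back((int)(it->first % (uint64_t)n));
      ori.push_back("+");
    }
  }
  for (std::unordered_map<uint64_t, int>::const_iterator it = rev.m.begin();
       it != rev.m.end(); ++it) {
    if (it->second >= min_hits) {
      oi.push_back((int)(it->first / (uint64_t)n));
      oj.push_back((int)(it->first % (uint64_t)n));
      ori.push_back("-");
    }
  }
  return List::create(_["i"] = oi, _["j"] = oj, _["orientation"] = ori,
                      _["n_windows"] = (int)n);
}
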