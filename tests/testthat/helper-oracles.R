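# Independent oracles the implementation is checked against.

# Exhaustive double-loop Hamming scan over all seed offset pairs,
# vectorized position-by-position; any seed containing N fails.
oracle_seed_count <- function(a, b, seed_len, max_mm) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av) - seed_len + 1
  nb <- length(bv) - seed_len + 1
  A <- vapply(seq_len(seed_len), function(k) av[seq_len(na) + k - 1],
              character(na))
  B <- vapply(seq_len(seed_len), function(k) bv[seq_len(nb) + k - 1],
              character(nb))
  if (na == 1) A <- matrix(A, nrow = 1)
  if (nb == 1) B <- matrix(B, nrow = 1)
  mm <- matrix(0L, na, nb)
  for (k in seq_len(seed_len)) {
    mm <- mm + outer(A[, k], B[, k], "!=")
  }
  ok <- mm <= max_mm
  ok[apply(A == "N", 1, any), ] <- FALSE
  ok[, apply(B == "N", 1, any)] <- FALSE
  sum(ok)
}

# Per-base bitmap union of 0-based half-open intervals.
oracle_union_length <- function(starts, ends, region_len) {
  hit <- logical(region_len)
  for (k in seq_along(starts)) {
    if (ends[k] > starts[k]) hit[(starts[k] + 1):ends[k]] <- TRUE
  }
  sum(hit)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute `k` random positions of a DNA string with different bases
substitute_bases <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  at <- sample(length(chars), k)
  for (i in at) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

# best identity (%) of a consensus against a prototype in either orientation
both_strand_identity <- function(consensus, prototype) {
  max(100 - pairwise_divergence(consensus, prototype),
      100 - pairwise_divergence(consensus, reverse_complement(prototype)))
}

# dot matrix built directly from a dot tibble, for run-extraction tests
make_dot_matrix <- function(dots, n_windows, window_bp = 300L) {
  cfg <- dotplot_config("fine", window_bp = window_bp)
  repcore:::new_dot_matrix(dots, n_windows = n_windows, config = cfg,
                           region_name = "test", region_len =
                             n_windows * window_bp)
}
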