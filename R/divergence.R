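#' Pairwise divergence of two DNA sequences
#'
#' Global alignment of the two sequences (exact banded alignment under unit
#' costs); divergence is the percentage of alignment columns that are
#' mismatches or gaps -- mutations plus insertions/deletions over the
#' compared columns. Symmetric, zero iff the sequences are identical.
#'
#' @param a,b Non-empty DNA strings.
#' @return Divergence as a percentage in `[0, 100]`.
#' @export
pairwise_divergence <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  cnt <- align_counts_cpp(toupper(a), toupper(b))
  100 * (cnt[["mismatches"]] + cnt[["gaps"]]) / cnt[["columns"]]
}

#' Extract strand-normalized occurrence sequences
#'
#' Slices each occurrence out of the region; minus-strand occurrences are
#' reverse-complemented so all copies read in core orientation.
#'
#' @param occurrences Occurrence table from [map_core_occurrences()].
#' @param region One-row region tibble.
#' @return `occurrences` with a `seq` column.
#' @export
occurrence_sequences <- function(occurrences, region) {
  seqs <- stringr::str_sub(region$seq[[1]], occurrences$start + 1L,
                           occurrences$end)
  minus <- occurrences$strand == "-"
  if (any(minus)) seqs[minus] <- reverse_complement(seqs[minus])
  dplyr::mutate(occurrences, seq = seqs)
}

#' Mean pairwise divergence within one group of copies
#'
#' @param seqs Character vector of strand-normalized copy sequences
#'   (at least 2).
#' @param max_pairs Cap on the number of aligned pairs; when a group has
#'   more unordered pairs than this, an evenly spaced deterministic subset
#'   is aligned. `Inf` aligns all pairs.
#' @return Mean of the pairwise divergences (percent).
#' @export
group_divergence <- function(seqs, max_pairs = Inf) {
  if (length(seqs) < 2) stop("need at least two occurrence sequences")
  pairs <- combn(length(seqs), 2)
  np <- ncol(pairs)
  if (is.finite(max_pairs) && np > max_pairs) {
    sel <- unique(round(seq(1, np, length.out = max_pairs)))
    pairs <- pairs[, sel, drop = FALSE]
  }
  mean(vapply(seq_len(ncol(pairs)), function(k) {
    pairwise_divergence(seqs[pairs[1, k]], seqs[pairs[2, k]])
  }, numeric(1)))
}

#' Divergence summary for every core element
#'
#' Computes the mean pairwise divergence among the mapped copies of each
#' core element (minus-strand copies reverse-complemented first). Cores
#' with fewer than two occurrences get `NA` with a flag; cores on an
#' exclusion list (e.g. ones whose sequence is contained within another
#' core) are dropped.
#'
#' @param occurrences Occurrence table from [map_core_occurrences()].
#' @param region One-row region tibble.
#' @param classes Optional tibble `(core_id, class)` (e.g. from
#'   [core_cnv()]) merged into the output.
#' @param exclude Character vector of core ids to drop.
#' @param max_pairs Per-core cap on aligned pairs (see
#'   [group_divergence()]); default 200.
#' @return A tibble `(core_id, n_occurrences, mean_divergence, defined,
#'   class)`.
#' @export
divergence_summary <- function(occurrences, region, classes = NULL,
                               exclude = NULL, max_pairs = 200) {
  occ <- occurrence_sequences(occurrences, region)
  if (!is.null(exclude)) {
    occ <- dplyr::filter(occ, !(.data$core_id %in% exclude))
  }
  out <- occ |>
    dplyr::group_by(.data$core_id) |>
    dplyr::summarise(
      n_occurrences = dplyr::n(),
      mean_divergence = if (dplyr::n() >= 2) {
        group_divergence(.data$seq, max_pairs = max_pairs)
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(defined = !is.na(.data$mean_divergence))
  if (!is.null(classes)) {
    out <- dplyr::left_join(out, classes, by = "core_id")
  }
  out
}

#' Compare divergence between CNV-type and constant-type cores
#'
#' Class means plus a two-sample two-sided Welch t test. With a
#' single-element class the means are still reported and the test is
#' flagged unreliable (`p = NA`).
#'
#' @param summaries Divergence summary with a `class` column (see
#'   [divergence_summary()]).
#' @param classes Which two class labels to compare.
#' @return A one-row tibble `(mean_a, mean_b, n_a, n_b, p, reliable)`
#'   where `a` is the first label in `classes`.
#' @export
compare_types <- function(summaries, classes = c("CNV", "constant")) {
  x <- summaries$mean_divergence[summaries$class == classes[[1]] &
                                   summaries$defined]
  y <- summaries$mean_divergence[summaries$class == classes[[2]] &
                                   summaries$defined]
  if (length(x) == 0 || length(y) == 0) {
    stop("both classes must be non-empty")
  }
  reliable <- length(x) >= 2 && length(y) >= 2 &&
    (var(x) > 0 || var(y) > 0)
  p <- if (reliable) t.test(x, y)$p.value else NA_real_
  tibble(mean_a = mean(x), mean_b = mean(y),
         n_a = length(x), n_b = length(y), p = p, reliable = reliable)
}

#' Correlation of divergence with duplication count
#'
#' Pearson correlation between each core's mean pairwise divergence and its
#' number of mapped occurrences.
#'
#' @param summaries Divergence summary (see [divergence_summary()]).
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
divergence_copy_correlation <- function(summaries) {
  df <- dplyr::filter(summaries, .data$defined)
  if (nrow(df) < 3) stop("need at least three cores with defined divergence")
  if (var(df$mean_divergence) == 0 || var(df$n_occurrences) == 0) {
    stop("zero variance in divergence or occurrence counts")
  }
  cor(df$mean_divergence, df$n_occurrences)
}

#' Plot divergence by class and against duplication count
#'
#' @param summaries Divergence summary with `class` (for
#'   `plot_divergence_by_class()`).
#' @return A ggplot object.
#' @export
plot_divergence_by_class <- function(summaries) {
  df <- dplyr::filter(summaries, .data$defined, !is.na(.data$class))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class,
                                   y = .data$mean_divergence)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "mean pairwise divergence (%)")
}

#' @rdname plot_divergence_by_class
#' @export
plot_divergence_vs_copies <- function(summaries) {
  df <- dplyr::filter(summaries, .data$defined)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_occurrences,
                                   y = .data$mean_divergence)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red3") +
    ggplot2::labs(x = "number of occurrences",
                  y = "mean pairwise divergence (%)")
}
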