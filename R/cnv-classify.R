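#' Read / write an aCGH probe table
#'
#' Tab-separated with a header line; columns `probe_id`, `chrom`, `start`,
#' `end` (0-based half-open), `comparison` (e.g. `"BLG2_vs_B6"`),
#' `replicate`, `log2_ratio`.
#'
#' @param probes Probe tibble.
#' @param path File path.
#' @return A probe tibble (`read_probe_table()`); `path` invisibly
#'   (`write_probe_table()`).
#' @export
read_probe_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    probe_id = "c", chrom = "c", start = "i", end = "i",
    comparison = "c", replicate = "i", log2_ratio = "d"
  ), progress = FALSE)
}

#' @rdname read_probe_table
#' @export
write_probe_table <- function(probes, path) {
  readr::write_tsv(probes, path)
  invisible(path)
}

#' Assign probes to core elements
#'
#' A probe is assigned to a core element when its midpoint falls inside any
#' occurrence of that core; a probe can map to several cores when
#' occurrences overlap, and probes outside all occurrences stay unassigned.
#'
#' @param probes Probe tibble (see [read_probe_table()]).
#' @param occurrences Occurrence table from [map_core_occurrences()].
#' @return The probe rows joined with a `core_id` column, one row per
#'   (probe, comparison, replicate, core) assignment.
#' @export
map_probes_to_cores <- function(probes, occurrences) {
  mid <- (probes$start + probes$end) %/% 2L
  qh <- IRanges::findOverlaps(
    IRanges::IRanges(start = mid + 1L, width = 1L),
    IRanges::IRanges(start = occurrences$start + 1L, end = occurrences$end)
  )
  assigned <- probes[S4Vectors::queryHits(qh), , drop = FALSE]
  assigned$core_id <- occurrences$core_id[S4Vectors::subjectHits(qh)]
  # a probe may hit several occurrences of the same core; count it once
  dplyr::distinct(as_tibble(assigned))
}

#' One-sample t test of mean log2 ratio against zero
#'
#' The statistic is `t = mean * sqrt(n / U)` with `U` the unbiased sample
#' variance, and the p-value the two-sided tail of Student's t with `n - 1`
#' degrees of freedom -- the classical one-sample t test of the null
#' hypothesis that the mean probe log2 ratio is zero (no copy-number
#' difference).
#'
#' @param values Numeric vector of probe log2 ratios (`n >= 2`).
#' @return A one-row tibble `(n, mean, var_unbiased, t, df, p, degenerate)`.
#'   With zero variance the result is degenerate: `p = 0` when the mean is
#'   nonzero, `t = 0, p = 1` when it is zero.
#' @export
core_t_test <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least two probe values")
  m <- mean(values)
  u <- var(values)
  if (u == 0) {
    if (m == 0) {
      return(tibble(n = n, mean = m, var_unbiased = 0, t = 0,
                    df = n - 1L, p = 1, degenerate = TRUE))
    }
    return(tibble(n = n, mean = m, var_unbiased = 0,
                  t = sign(m) * Inf, df = n - 1L, p = 0, degenerate = TRUE))
  }
  t <- m * sqrt(n / u)
  tibble(n = n, mean = m, var_unbiased = u, t = t, df = n - 1L,
         p = 2 * pt(-abs(t), df = n - 1), degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p P-value(s) in `[0, 1]`.
#' @param n_tests Number of tests in the family.
#' @return `min(1, p * n_tests)`, vectorized over `p`.
#' @export
bonferroni_adjust <- function(p, n_tests) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p outside [0, 1]")
  if (n_tests < 1) stop("n_tests must be >= 1")
  pmin(1, p * n_tests)
}

#' Classify a core element from two strain comparisons
#'
#' `insufficient` when either comparison has fewer than `min_probes` probes;
#' otherwise `CNV` when the adjusted p-value is below `alpha` in both
#' comparisons, `constant` when in neither, `single_pair` when in exactly
#' one. Symmetric in the two comparisons.
#'
#' @param p_adj_a,p_adj_b Adjusted p-values of the two comparisons.
#' @param n_a,n_b Probe counts of the two comparisons.
#' @param alpha Significance level.
#' @param min_probes Minimum probes per comparison.
#' @return Character vector of class labels (vectorized).
#' @export
classify_core <- function(p_adj_a, p_adj_b, n_a, n_b, alpha = 0.05,
                          min_probes = 30L) {
  sig_a <- p_adj_a < alpha
  sig_b <- p_adj_b < alpha
  dplyr::case_when(
    n_a < min_probes | n_b < min_probes ~ "insufficient",
    sig_a & sig_b ~ "CNV",
    !sig_a & !sig_b ~ "constant",
    TRUE ~ "single_pair"
  )
}

#' Per-core average log2 ratios
#'
#' @param mapped Mapped probe table from [map_probes_to_cores()].
#' @param order_by Comparison label whose means define the sort order
#'   (descending); defaults to the first comparison alphabetically.
#' @return A tibble with one row per core, one column of mean log2 per
#'   comparison, sorted by the ordering comparison's mean.
#' @export
average_log2 <- function(mapped, order_by = NULL) {
  means <- mapped |>
    dplyr::group_by(.data$core_id, .data$comparison) |>
    dplyr::summarise(mean_log2 = mean(.data$log2_ratio), .groups = "drop")
  if (is.null(order_by)) order_by <- sort(unique(means$comparison))[[1]]
  wide <- tidyr::pivot_wider(means, names_from = "comparison",
                             values_from = "mean_log2")
  dplyr::arrange(wide, dplyr::desc(.data[[order_by]]))
}

#' Classify core elements as CNV-type or constant-type from aCGH probes
#'
#' End-to-end copy-number classification: assigns probes to core elements by
#' occurrence overlap, optionally pools replicate measurements per probe,
#' runs the one-sample t test of the mean log2 ratio against zero for every
#' core and comparison, applies Bonferroni correction across cores, and
#' labels each core `CNV`, `constant`, `single_pair` or `insufficient`.
#'
#' @param probes Probe tibble (see [read_probe_table()]).
#' @param occurrences Occurrence table from [map_core_occurrences()].
#' @param alpha Significance level on the adjusted p-value.
#' @param min_probes Minimum probes per comparison for a core to be
#'   testable.
#' @param n_tests Bonferroni family size; `NULL` (default) uses the number
#'   of testable cores per comparison, an explicit integer overrides it.
#' @param pool_replicates Average replicate measurements per probe before
#'   testing (default), avoiding pseudo-replication; `FALSE` treats every
#'   replicate measurement as an independent observation.
#' @param comparisons The two comparison labels to classify on; defaults to
#'   the first two present.
#' @return An object of class `core_cnv`; see [tidy.core_cnv()] and
#'   [glance.core_cnv()].
#' @export
core_cnv <- function(probes, occurrences, alpha = 0.05, min_probes = 30L,
                     n_tests = NULL, pool_replicates = TRUE,
                     comparisons = NULL) {
  mapped <- map_probes_to_cores(probes, occurrences)
  if (is.null(comparisons)) {
    comparisons <- sort(unique(mapped$comparison))
  }
  if (length(comparisons) != 2) {
    stop("core_cnv classifies on exactly two strain comparisons; got ",
         length(comparisons))
  }
  mapped <- dplyr::filter(mapped, .data$comparison %in% comparisons)
  if (pool_replicates) {
    mapped <- mapped |>
      dplyr::group_by(.data$core_id, .data$comparison, .data$probe_id) |>
      dplyr::summarise(log2_ratio = mean(.data$log2_ratio),
                       .groups = "drop")
  }
  stats <- mapped |>
    dplyr::group_by(.data$core_id, .data$comparison) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(core_t_test(.data$log2_ratio), .groups = "drop")
  counts <- mapped |>
    dplyr::count(.data$core_id, .data$comparison, name = "n_probes")
  stats <- stats |>
    dplyr::group_by(.data$comparison) |>
    dplyr::mutate(
      n_testable = sum(.data$n >= min_probes),
      p_adj = bonferroni_adjust(
        .data$p,
        if (is.null(n_tests)) max(1L, .data$n_testable[[1]])
        else as.integer(n_tests)
      )
    ) |>
    dplyr::ungroup()
  wide <- stats |>
    dplyr::select("core_id", "comparison", "n", "p_adj") |>
    tidyr::pivot_wider(names_from = "comparison",
                       values_from = c("n", "p_adj"))
  na <- wide[[paste0("n_", comparisons[[1]])]]
  nb <- wide[[paste0("n_", comparisons[[2]])]]
  pa <- wide[[paste0("p_adj_", comparisons[[1]])]]
  pb <- wide[[paste0("p_adj_", comparisons[[2]])]]
  na[is.na(na)] <- 0L
  nb[is.na(nb)] <- 0L
  classes <- tibble(
    core_id = wide$core_id,
    class = classify_core(dplyr::coalesce(pa, 1), dplyr::coalesce(pb, 1),
                          na, nb, alpha = alpha, min_probes = min_probes)
  )
  # cores with occurrences but too few mapped probes in some comparison
  all_cores <- unique(occurrences$core_id)
  missing <- setdiff(all_cores, classes$core_id)
  if (length(missing) > 0) {
    classes <- dplyr::bind_rows(
      classes, tibble(core_id = missing, class = "insufficient")
    )
  }
  structure(
    list(stats = stats, classes = dplyr::arrange(classes, .data$core_id),
         mapped = mapped,
         params = list(alpha = alpha, min_probes = min_probes,
                       n_tests = n_tests, comparisons = comparisons,
                       pool_replicates = pool_replicates)),
    class = "core_cnv"
  )
}

#' @export
print.core_cnv <- function(x, ...) {
  tab <- table(x$classes$class)
  cat("Core-element CNV classification (",
      paste(x$params$comparisons, collapse = " & "), ")\n", sep = "")
  cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Tidy and summarize a `core_cnv` fit
#'
#' `tidy()` returns one row per core and comparison with the probe count,
#' mean, unbiased variance, t statistic, degrees of freedom, raw and
#' Bonferroni-adjusted p-values, plus the core's class label. `glance()`
#' returns a one-row summary with the class tallies.
#'
#' @param x A `core_cnv` object.
#' @param ... Ignored.
#' @return A tibble.
#' @export
tidy.core_cnv <- function(x, ...) {
  dplyr::left_join(x$stats, x$classes, by = "core_id") |>
    dplyr::select("core_id", "comparison", "n", "mean", "var_unbiased",
                  "t", "df", "p", "p_adj", "degenerate", "class")
}

#' @rdname tidy.core_cnv
#' @export
glance.core_cnv <- function(x, ...) {
  cls <- x$classes$class
  tibble(
    n_cores = length(cls),
    n_cnv = sum(cls == "CNV"),
    n_constant = sum(cls == "constant"),
    n_single_pair = sum(cls == "single_pair"),
    n_insufficient = sum(cls == "insufficient"),
    alpha = x$params$alpha,
    min_probes = x$params$min_probes
  )
}

#' Plot per-core mean log2 ratios by class
#'
#' Cores ordered by the mean log2 ratio of the first comparison; one point
#' per comparison, coloured by class label.
#'
#' @param object A `core_cnv` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.core_cnv <- function(object, ...) {
  df <- tidy(object)
  ord <- df |>
    dplyr::filter(.data$comparison == object$params$comparisons[[1]]) |>
    dplyr::arrange(dplyr::desc(.data$mean))
  df$core_id <- factor(df$core_id, levels = ord$core_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$core_id, y = .data$mean,
                                   colour = .data$class,
                                   shape = .data$comparison)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "core element", y = "mean probe log2 ratio",
                  colour = "class", shape = "comparison") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
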