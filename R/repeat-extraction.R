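#' Extract maximal diagonal runs from a dot matrix
#'
#' A repetitive sequence shows up in the self-comparative plot as a diagonal
#' line: consecutive forward dots step `(i+1, j+1)`, reverse (anti-diagonal)
#' dots step `(i+1, j-1)`. Every maximal run of at least `min_run`
#' consecutive same-orientation dots in the upper triangle (`i < j`) is
#' returned exactly once.
#'
#' @param dots A `dot_matrix` from [build_self_dotplot()].
#' @param min_run Minimum number of consecutive dots (default 3).
#' @return A tibble with one row per run: `orientation`, `start_i`,
#'   `start_j`, `n_dots`, plus the genomic footprints `qstart`, `qend`
#'   (row axis) and `mstart`, `mend` (column axis), 0-based half-open,
#'   sorted by `(qstart, mstart)`. Carries the `window_bp` attribute.
#' @export
extract_diagonal_runs <- function(dots, min_run = 3L) {
  if (min_run < 1) stop("min_run must be >= 1")
  w <- attr(dots, "window_bp")
  if (is.null(w)) stop("`dots` must be a dot_matrix (missing window_bp)")
  up <- dplyr::filter(as_tibble(dots), .data$i < .data$j)
  if (nrow(up) == 0) {
    runs <- tibble(orientation = character(), start_i = integer(),
                   start_j = integer(), n_dots = integer(),
                   qstart = integer(), qend = integer(),
                   mstart = integer(), mend = integer())
    attr(runs, "window_bp") <- w
    return(runs)
  }
  runs <- up |>
    dplyr::mutate(diag = ifelse(.data$orientation == "+",
                                .data$j - .data$i, .data$j + .data$i)) |>
    dplyr::group_by(.data$orientation, .data$diag) |>
    dplyr::arrange(.data$i, .by_group = TRUE) |>
    # consecutive i within one (anti-)diagonal form a run
    dplyr::mutate(brk = cumsum(c(1L, diff(.data$i) != 1L))) |>
    dplyr::group_by(.data$orientation, .data$diag, .data$brk) |>
    dplyr::summarise(start_i = min(.data$i),
                     start_j = dplyr::first(.data$j),
                     n_dots = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_dots >= min_run)
  runs <- runs |>
    dplyr::mutate(
      qstart = .data$start_i * w,
      qend = (.data$start_i + .data$n_dots) * w,
      mstart = ifelse(.data$orientation == "+",
                      .data$start_j * w,
                      (.data$start_j - .data$n_dots + 1L) * w),
      mend = ifelse(.data$orientation == "+",
                    (.data$start_j + .data$n_dots) * w,
                    (.data$start_j + 1L) * w)
    ) |>
    dplyr::select(-"diag", -"brk") |>
    dplyr::arrange(.data$qstart, .data$mstart)
  attr(runs, "window_bp") <- w
  runs
}

#' Convert diagonal runs into repetitive-sequence records
#'
#' Each run yields one repetitive sequence whose canonical interval is the
#' run's row-axis (query) footprint; the column-axis (mate) footprint is
#' retained for the row/column redundancy-elimination geometry. Reverse runs
#' carry strand `"-"` on the mate.
#'
#' @param runs Output of [extract_diagonal_runs()].
#' @return A tibble with columns `id`, `qstart`, `qend`, `mstart`, `mend`,
#'   `strand`, `n_dots`, `length_bp`.
#' @export
runs_to_repetitive_sequences <- function(runs) {
  out <- runs |>
    dplyr::transmute(
      id = dplyr::row_number(),
      qstart = .data$qstart, qend = .data$qend,
      mstart = .data$mstart, mend = .data$mend,
      strand = ifelse(.data$orientation == "+", "+", "-"),
      n_dots = .data$n_dots,
      length_bp = .data$qend - .data$qstart
    )
  attr(out, "window_bp") <- attr(runs, "window_bp")
  out
}

#' Length histogram of repetitive sequences
#'
#' @param repseqs Tibble with a `length_bp` column.
#' @param bin_bp Bin width in bp; lengths are binned by their lower edge.
#' @return A tibble `(bin, count)`; counts partition the input.
#' @export
length_histogram <- function(repseqs, bin_bp = 300L) {
  if (bin_bp <= 0) stop("bin_bp must be positive")
  if (nrow(repseqs) == 0) return(tibble(bin = integer(), count = integer()))
  repseqs |>
    dplyr::count(bin = (.data$length_bp %/% bin_bp) * bin_bp,
                 name = "count") |>
    dplyr::arrange(.data$bin)
}

#' @rdname length_histogram
#' @param ... Passed to [length_histogram()].
#' @return `plot_length_histogram()` returns a ggplot object.
#' @export
plot_length_histogram <- function(repseqs, bin_bp = 300L, ...) {
  h <- length_histogram(repseqs, bin_bp = bin_bp)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin / 1000, y = .data$count)) +
    ggplot2::geom_col(width = bin_bp / 1000, just = 0, fill = "grey30") +
    ggplot2::labs(x = "repetitive sequence length (kbp)", y = "count")
}

interval_union_length <- function(starts, ends) {
  if (length(starts) == 0) return(0L)
  # IRanges is 1-based closed; shift half-open [s, e) to [s+1, e]
  sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = starts + 1L, end = ends)
  )))
}

#' Coverage of the region as a function of a length threshold
#'
#' For each grid length `L`, computes the fraction of the region covered by
#' the union of the query and mate footprints of the repetitive sequences
#' passing the filter: `length_bp >= L` for `sweep = "min"` (coverage is
#' non-increasing in `L`), `length_bp <= L` for `sweep = "max"`
#' (non-decreasing). Both footprints count, since a repeat is present at
#' both loci.
#'
#' @param repseqs Repetitive-sequence tibble from
#'   [runs_to_repetitive_sequences()].
#' @param region_len Region length in bp.
#' @param sweep `"min"` or `"max"`: which length bound the grid sweeps.
#' @param grid Numeric vector of length thresholds in bp.
#' @return A tibble `(length, coverage)` with coverage in `[0, 1]`.
#' @export
coverage_curve <- function(repseqs, region_len,
                           sweep = c("min", "max"), grid) {
  sweep <- match.arg(sweep)
  if (length(grid) == 0) stop("empty grid")
  if (region_len <= 0) stop("region_len must be positive")
  cov_at <- function(L) {
    keep <- if (sweep == "min") repseqs$length_bp >= L
            else repseqs$length_bp <= L
    sel <- repseqs[keep, , drop = FALSE]
    interval_union_length(c(sel$qstart, sel$mstart),
                          c(sel$qend, sel$mend)) / region_len
  }
  tibble(length = as.numeric(grid),
         coverage = vapply(grid, cov_at, numeric(1)))
}

#' @rdname coverage_curve
#' @return `plot_coverage_curve()` returns a ggplot object overlaying the
#'   min-length and max-length sweeps.
#' @export
plot_coverage_curve <- function(repseqs, region_len, grid) {
  df <- dplyr::bind_rows(
    dplyr::mutate(coverage_curve(repseqs, region_len, "min", grid),
                  sweep = "minimum length"),
    dplyr::mutate(coverage_curve(repseqs, region_len, "max", grid),
                  sweep = "maximum length")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length / 1000,
                                   y = .data$coverage,
                                   colour = .data$sweep)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c("minimum length" = "red3",
                                            "maximum length" = "blue3")) +
    ggplot2::labs(x = "length threshold (kbp)", y = "coverage of region",
                  colour = NULL) +
    ggplot2::ylim(0, 1)
}
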