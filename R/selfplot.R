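#' Configuration for the self-comparative dot-plot
#'
#' Two presets mirror the two analysis granularities: `"fine"` declares a dot
#' for a pair of 300-bp windows sharing at least one 30-bp seed with at most
#' 2 mismatches; `"coarse"` uses 3,000-bp windows requiring more than three
#' such seeds. Dots closer to the main diagonal than `min_offset_bp` are
#' suppressed (in fine mode the offset equals the window so the trivial
#' self-match band never appears).
#'
#' @param mode `"fine"` or `"coarse"`; sets the defaults below.
#' @param window_bp Window size in bp (non-overlapping tiles).
#' @param seed_len Seed length in bp.
#' @param max_mismatches Maximum Hamming mismatches tolerated in a seed.
#' @param min_seed_hits Number of shared seeds required to declare a dot.
#' @param min_offset_bp Minimum distance in bp between paired windows.
#' @param search_reverse Also search each window against the reverse
#'   complement of the other.
#' @return A list of class `dotplot_config`.
#' @export
dotplot_config <- function(mode = c("fine", "coarse"),
                           window_bp = NULL, seed_len = 30L,
                           max_mismatches = 2L, min_seed_hits = NULL,
                           min_offset_bp = NULL, search_reverse = TRUE) {
  mode <- match.arg(mode)
  if (is.null(window_bp)) window_bp <- if (mode == "fine") 300L else 3000L
  if (is.null(min_seed_hits)) min_seed_hits <- if (mode == "fine") 1L else 4L
  if (is.null(min_offset_bp)) {
    min_offset_bp <- if (mode == "fine") window_bp else 300L
  }
  stopifnot(seed_len <= window_bp, min_seed_hits >= 1,
            max_mismatches >= 0, max_mismatches < seed_len)
  structure(
    list(mode = mode, window_bp = as.integer(window_bp),
         seed_len = as.integer(seed_len),
         max_mismatches = as.integer(max_mismatches),
         min_seed_hits = as.integer(min_seed_hits),
         min_offset_bp = as.integer(min_offset_bp),
         search_reverse = isTRUE(search_reverse)),
    class = "dotplot_config"
  )
}

#' Count mismatch-tolerant seed matches between two windows
#'
#' Counts offset pairs `(p, q)` for which the `seed_len`-mers starting at `p`
#' in `a` and `q` in `b` differ at no more than `max_mismatches` positions.
#' Seeds containing `N` never match. The search is seeded (pigeonhole split
#' into `max_mismatches + 1` exact parts) but the count is exact, up to an
#' optional early-exit `cap`.
#'
#' @param a,b DNA strings, each at least `seed_len` long.
#' @param seed_len Seed length in bp.
#' @param max_mismatches Maximum mismatches per seed.
#' @param cap Stop counting once this many matches are found (`Inf` counts
#'   all).
#' @return Integer count of matching offset pairs.
#' @export
window_pair_matches <- function(a, b, seed_len = 30L, max_mismatches = 2L,
                                cap = Inf) {
  if (nchar(a) < seed_len || nchar(b) < seed_len) {
    stop("windows shorter than seed length")
  }
  capi <- if (is.finite(cap)) as.integer(cap) else 0L
  count_seed_matches_cpp(toupper(a), toupper(b), as.integer(seed_len),
                         as.integer(max_mismatches), capi)
}

#' Build the self-comparative dot matrix of a region
#'
#' Tiles the region into non-overlapping windows (the trailing partial window
#' is dropped) and declares a dot for every window pair satisfying the seed
#' criterion in [dotplot_config()]. Forward dots are stored symmetrically;
#' reverse dots record at `(i, j)` that window `i` matches the reverse
#' complement of window `j` (also a symmetric relation).
#'
#' @param region One-row region tibble (see [read_fasta()]) or a bare DNA
#'   string.
#' @param config A [dotplot_config()].
#' @return A tibble of class `dot_matrix` with columns `i`, `j` (0-based
#'   window indices) and `orientation` (`"+"` or `"-"`), sorted by
#'   `(i, j)`, carrying `n_windows`, `window_bp`, `region_name`,
#'   `region_len` and `config` attributes.
#' @export
build_self_dotplot <- function(region, config = dotplot_config("fine")) {
  if (is.character(region) && length(region) == 1) region <- as_region(region)
  seq <- toupper(region$seq[[1]])
  if (nchar(seq) < 2L * config$window_bp) {
    stop("region shorter than two windows")
  }
  res <- self_dotplot_cpp(seq, config$window_bp, config$seed_len,
                          config$max_mismatches, config$min_seed_hits,
                          config$min_offset_bp, config$search_reverse)
  dots <- tibble(i = res$i, j = res$j, orientation = res$orientation)
  # mirror the upper-triangle dots
  dots <- dplyr::bind_rows(
    dots,
    tibble(i = dots$j, j = dots$i, orientation = dots$orientation)
  )
  dots <- dplyr::arrange(dplyr::distinct(dots), .data$i, .data$j,
                         .data$orientation)
  new_dot_matrix(dots, n_windows = res$n_windows, config = config,
                 region_name = region$name[[1]], region_len = nchar(seq))
}

new_dot_matrix <- function(dots, n_windows, config, region_name, region_len) {
  structure(
    dots,
    n_windows = as.integer(n_windows),
    window_bp = config$window_bp,
    config = config,
    region_name = region_name,
    region_len = as.integer(region_len),
    class = c("dot_matrix", class(tibble()))
  )
}

#' @export
print.dot_matrix <- function(x, ...) {
  cat(sprintf(
    "# Self-comparative dot matrix: %d windows of %d bp (%s), %d dots\n",
    attr(x, "n_windows"), attr(x, "window_bp"),
    attr(x, "region_name"), nrow(x)
  ))
  NextMethod()
}

#' Export / import a dot matrix as TSV
#'
#' Header comment lines record the window size and seed criterion so that
#' `read_dots()` reproduces the matrix exactly.
#'
#' @param dots A `dot_matrix` from [build_self_dotplot()].
#' @param path File path.
#' @return `export_dots()` returns `path` invisibly; `read_dots()` returns
#'   the `dot_matrix`.
#' @export
export_dots <- function(dots, path) {
  cfg <- attr(dots, "config")
  hdr <- sprintf(
    paste0("# repcore dot matrix\n# region=%s region_len=%d n_windows=%d\n",
           "# window_bp=%d seed_len=%d max_mismatches=%d min_seed_hits=%d ",
           "min_offset_bp=%d search_reverse=%s mode=%s\n"),
    attr(dots, "region_name"), attr(dots, "region_len"),
    attr(dots, "n_windows"),
    cfg$window_bp, cfg$seed_len, cfg$max_mismatches, cfg$min_seed_hits,
    cfg$min_offset_bp, cfg$search_reverse, cfg$mode
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sub("\n$", "", hdr), con)
  writeLines("i\tj\torientation", con)
  if (nrow(dots) > 0) {
    writeLines(paste(dots$i, dots$j, dots$orientation, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname export_dots
#' @export
read_dots <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  kv <- stringr::str_match_all(paste(meta, collapse = " "),
                               "(\\S+)=(\\S+)")[[1]]
  vals <- setNames(kv[, 3], kv[, 2])
  cfg <- dotplot_config(
    mode = vals[["mode"]],
    window_bp = as.integer(vals[["window_bp"]]),
    seed_len = as.integer(vals[["seed_len"]]),
    max_mismatches = as.integer(vals[["max_mismatches"]]),
    min_seed_hits = as.integer(vals[["min_seed_hits"]]),
    min_offset_bp = as.integer(vals[["min_offset_bp"]]),
    search_reverse = as.logical(vals[["search_reverse"]])
  )
  body <- lines[!startsWith(lines, "#")]
  df <- readr::read_tsv(I(paste(body, collapse = "\n")),
                        col_types = "iic", progress = FALSE)
  new_dot_matrix(as_tibble(df), n_windows = as.integer(vals[["n_windows"]]),
                 config = cfg, region_name = vals[["region"]],
                 region_len = as.integer(vals[["region_len"]]))
}

#' Plot a dot matrix
#'
#' Sparse rendering of the self-comparative plot; forward dots in one colour,
#' reverse dots in another, the y axis flipped so the main diagonal runs
#' top-left to bottom-right as in conventional dot-plots.
#'
#' @param object A `dot_matrix`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.dot_matrix <- function(object, ...) {
  w <- attr(object, "window_bp")
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j * w, y = .data$i * w,
                                   colour = .data$orientation)) +
    ggplot2::geom_point(shape = 15, size = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_colour_manual(values = c("+" = "grey20", "-" = "red3")) +
    ggplot2::labs(x = "position (bp)", y = "position (bp)",
                  colour = "orientation",
                  title = sprintf("Self-comparative plot: %s",
                                  attr(object, "region_name")))
}
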