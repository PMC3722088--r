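#' Pipeline configuration
#'
#' Bundles every stage's parameters with the workflow defaults: 300-bp
#' windows with 30-bp seeds and at most 2 mismatches, runs of at least 3
#' dots, a 3--4.5 kbp fundamental length window, 50% row/column overlap
#' tolerance, a 2.7-kbp / 70%-identity clustering threshold, >1 kbp
#' gap-free consensus cores, 70%-identity occurrence mapping, and CNV
#' classification at alpha 0.05 with at least 30 probes per core.
#'
#' @param dotplot A [dotplot_config()].
#' @param min_run Minimum dots per diagonal run.
#' @param fundamental_lo_bp,fundamental_hi_bp Fundamental length window.
#' @param overlap_frac Row/column elimination overlap tolerance.
#' @param min_shared_bp,min_cluster_identity Clustering match thresholds.
#' @param min_core_len_bp Minimum gap-free consensus length (strict).
#' @param majority_frac Consensus column support threshold (strict).
#' @param min_occurrence_identity,min_occurrence_cov Occurrence-mapping
#'   thresholds.
#' @param alpha,min_probes,n_tests CNV classification parameters (see
#'   [core_cnv()]).
#' @param divergence_max_pairs Per-core cap on divergence alignments.
#' @param aligner An [aligner_config()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(dotplot = dotplot_config("fine"),
                            min_run = 3L,
                            fundamental_lo_bp = 3000L,
                            fundamental_hi_bp = 4500L,
                            overlap_frac = 0.5,
                            min_shared_bp = 2700L,
                            min_cluster_identity = 0.7,
                            min_core_len_bp = 1000L,
                            majority_frac = 0.5,
                            min_occurrence_identity = 0.70,
                            min_occurrence_cov = 0.5,
                            alpha = 0.05, min_probes = 30L, n_tests = NULL,
                            divergence_max_pairs = 200,
                            aligner = aligner_config()) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the whole core-element workflow on a region
#'
#' Chains every stage: self-comparative dot-plot, diagonal-run extraction,
#' length filtering, row/column redundancy elimination, pair scoring,
#' clustering, consensus core derivation, occurrence mapping, coverage,
#' and -- when a probe table is supplied -- CNV classification and
#' within-core divergence. A missing probe table skips the CNV stage with a
#' warning and leaves the upstream results intact.
#'
#' @param region One-row region tibble (see [read_fasta()]).
#' @param probes Optional probe tibble (see [read_probe_table()]).
#' @param config A [pipeline_config()].
#' @return A list of class `sd_pipeline` with elements `dots`, `repseqs`,
#'   `fundamentals`, `scores`, `groups`, `cores`, `occurrences`,
#'   `coverage`, `cnv` (or `NULL`), `divergence` (or `NULL`), `summary`
#'   (stage-count tibble) and `config`.
#' @export
run_pipeline <- function(region, probes = NULL,
                         config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dots <- stage("selfplot", build_self_dotplot(region, config$dotplot))
  runs <- stage("extract", extract_diagonal_runs(dots, config$min_run))
  repseqs <- stage("extract", runs_to_repetitive_sequences(runs))
  in_window <- stage("fundamentals", filter_by_length(
    repseqs, config$fundamental_lo_bp, config$fundamental_hi_bp))
  fund <- stage("fundamentals",
                eliminate_redundant(in_window, config$overlap_frac))
  fund <- repseq_sequences(fund, region)
  scores <- stage("cluster", score_pairs(fund, config$aligner))
  groups <- stage("cluster", cluster_fundamentals(
    scores, ids = fund$id, min_shared_bp = config$min_shared_bp,
    min_identity = config$min_cluster_identity))
  cores <- stage("cores", derive_core_elements(
    groups, fund, min_len_bp = config$min_core_len_bp,
    majority_frac = config$majority_frac, config = config$aligner))
  occurrences <- stage("map", map_core_occurrences(
    cores, region, min_identity = config$min_occurrence_identity,
    min_cov_frac = config$min_occurrence_cov, config = config$aligner))
  coverage <- region_coverage(occurrences, region$length[[1]])

  cnv <- NULL
  divergence <- NULL
  if (is.null(probes)) {
    warning("no probe table supplied; CNV classification skipped")
  } else {
    cnv <- stage("cnv", core_cnv(probes, occurrences,
                                 alpha = config$alpha,
                                 min_probes = config$min_probes,
                                 n_tests = config$n_tests))
  }
  if (nrow(occurrences) > 0) {
    divergence <- stage("diverge", divergence_summary(
      occurrences, region, classes = if (!is.null(cnv)) cnv$classes,
      max_pairs = config$divergence_max_pairs))
  }

  summary <- tibble(
    stage = c("windows", "dots", "diagonal_runs", "repetitive_sequences",
              "in_length_window", "fundamentals", "groups", "cores",
              "occurrences"),
    count = c(attr(dots, "n_windows"), nrow(dots), nrow(runs),
              nrow(repseqs), nrow(in_window), nrow(fund),
              length(unique(groups$group)), nrow(cores),
              nrow(occurrences))
  )
  structure(
    list(dots = dots, repseqs = repseqs, in_window = in_window,
         fundamentals = fund, scores = scores, groups = groups,
         cores = cores, occurrences = occurrences, coverage = coverage,
         cnv = cnv, divergence = divergence, summary = summary,
         config = config, region_name = region$name[[1]],
         region_len = region$length[[1]]),
    class = "sd_pipeline"
  )
}

#' @export
print.sd_pipeline <- function(x, ...) {
  cat(sprintf("Core-element pipeline on %s (%d bp)\n", x$region_name,
              x$region_len))
  for (r in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-22s %d\n", x$summary$stage[r], x$summary$count[r]))
  }
  cat(sprintf("  occurrence coverage    %.1f%%\n", 100 * x$coverage))
  if (!is.null(x$cnv)) {
    tab <- table(x$cnv$classes$class)
    cat("  CNV classes:", paste(sprintf("%s=%d", names(tab),
                                        as.integer(tab)), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits `dots.tsv`, `repseqs.tsv`, `fundamentals.tsv`, `groups.tsv`,
#' `cores.fasta`, `occurrences.bed` (score = identity x 1000),
#' `cnv_calls.tsv` and `divergence.tsv` when available, plus
#' `run_summary.tsv`.
#'
#' @param result An `sd_pipeline` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  export_dots(result$dots, file.path(dir, "dots.tsv"))
  readr::write_tsv(result$repseqs, file.path(dir, "repseqs.tsv"))
  readr::write_tsv(dplyr::select(result$fundamentals, -"seq"),
                   file.path(dir, "fundamentals.tsv"))
  readr::write_tsv(result$groups, file.path(dir, "groups.tsv"))
  write_fasta(tibble(name = result$cores$core_id,
                     seq = result$cores$consensus),
              file.path(dir, "cores.fasta"))
  write_bed(tibble(chrom = result$region_name,
                   start = result$occurrences$start,
                   end = result$occurrences$end,
                   name = result$occurrences$core_id,
                   score = round(result$occurrences$identity * 1000),
                   strand = result$occurrences$strand),
            file.path(dir, "occurrences.bed"))
  if (!is.null(result$cnv)) {
    readr::write_tsv(tidy(result$cnv), file.path(dir, "cnv_calls.tsv"))
  }
  if (!is.null(result$divergence)) {
    readr::write_tsv(result$divergence, file.path(dir, "divergence.tsv"))
  }
  readr::write_tsv(result$summary, file.path(dir, "run_summary.tsv"))
  invisible(dir)
}
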