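#' Configuration for the planted-repeat simulator
#'
#' The generator emulates the structure the pipeline is built for: a random
#' background sequence carrying several repeat prototypes, each copied many
#' times with substitutions and single-base indels, in both orientations,
#' plus an aCGH-style probe table whose per-probe log2 ratios scatter
#' (Gaussian, in log2 units) around the log2 of the true copy ratio between
#' a test strain and the reference strain.
#'
#' Defaults: ten prototypes of 3.3--3.9 kbp, 5--30 copies each, 2%
#' substitutions and 0.2% single-base indels per copy, reverse orientation
#' with probability 0.5, copies separated by at least one window of
#' background, region sized to the planted content (~1 Mbp under defaults),
#' two strain comparisons with 100 probes per element, probe noise sd 0.3.
#'
#' @param seed Integer RNG seed; every simulation is reproducible from it.
#' @param region_len_bp Total region length; `NULL` sizes the region to the
#'   planted content plus ~15% background.
#' @param n_prototypes Number of repeat prototypes.
#' @param prototype_len_bp Length range `(lo, hi)` of prototypes.
#' @param copies_per_prototype Range `(lo, hi)` of copy counts (reference
#'   strain).
#' @param substitution_rate Per-base substitution probability per copy.
#' @param indel_rate Per-base probability of a single-base indel
#'   (insertion or deletion with equal probability).
#' @param reverse_prob Probability a copy is planted in reverse orientation.
#' @param spacer_bp Range of background spacer lengths between copies; the
#'   minimum must be at least one analysis window so runs from distinct
#'   copies cannot merge.
#' @param comparisons Labels of the strain comparisons.
#' @param cnv_prob,single_prob Per-prototype probability of being a
#'   CNV-type element (copy ratio differs from 1 in both comparisons) or a
#'   single-pair element (in exactly one); otherwise constant.
#' @param copy_ratios Pool of non-unit copy ratios (test/reference) drawn
#'   for varying elements.
#' @param probes_per_element Probes planted per prototype.
#' @param probe_len_bp Probe length range (isothermal tiling probes).
#' @param probe_noise_sd Gaussian noise sd on probe log2 ratios.
#' @param n_replicates Biological replicates per comparison.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, region_len_bp = NULL,
                       n_prototypes = 10L,
                       prototype_len_bp = c(3300L, 3900L),
                       copies_per_prototype = c(5L, 30L),
                       substitution_rate = 0.02, indel_rate = 0.002,
                       reverse_prob = 0.5, spacer_bp = c(500L, 2000L),
                       comparisons = c("BLG2_vs_B6", "MSM_vs_B6"),
                       cnv_prob = 0.8, single_prob = 0.05,
                       copy_ratios = c(0.5, 1.5, 2),
                       probes_per_element = 100L,
                       probe_len_bp = c(50L, 75L),
                       probe_noise_sd = 0.3, n_replicates = 2L) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            reverse_prob >= 0, reverse_prob <= 1,
            cnv_prob + single_prob <= 1)
  structure(as.list(environment()), class = "sim_config")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_copy <- function(seq, sub_rate, indel_rate) {
  chars <- stringr::str_split(seq, "")[[1]]
  n <- length(chars)
  sub_at <- which(runif(n) < sub_rate)
  n_sub <- length(sub_at)
  for (i in sub_at) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  indel_at <- which(runif(n) < indel_rate)
  n_indel <- length(indel_at)
  if (n_indel > 0) {
    pieces <- as.list(chars)
    for (i in indel_at) {
      if (runif(1) < 0.5) {
        pieces[[i]] <- "" # deletion
      } else {
        pieces[[i]] <- paste0(chars[i], sample(c("A", "C", "G", "T"), 1))
      }
    }
    chars <- unlist(strsplit(paste(unlist(pieces), collapse = ""), ""))
  }
  list(seq = paste(chars, collapse = ""), n_sub = n_sub, n_indel = n_indel)
}

#' Generate a region with planted repeat prototypes
#'
#' Draws a uniform-random background, plants mutated copies of
#' uniform-random prototypes in shuffled order with background spacers, and
#' records the full truth: prototype sequences, the realized interval,
#' strand and identity of every copy, and per-strain copy numbers per
#' prototype. Byte-identical for a given config.
#'
#' @param config A [sim_config()].
#' @return A list of class `sd_simulation` with elements `region` (one-row
#'   region tibble), `prototypes` (`prototype_id`, `length_bp`, `seq`,
#'   per-strain copy numbers and true log2 ratios, `true_class`),
#'   `occurrences` (`prototype_id`, `start`, `end`, `strand`, `identity`)
#'   and `config`.
#' @export
simulate_sd_region <- function(config = sim_config()) {
  set.seed(config$seed)
  k <- config$n_prototypes
  proto_len <- sample(config$prototype_len_bp[1]:config$prototype_len_bp[2],
                      k, replace = TRUE)
  protos <- vapply(proto_len, rand_dna, character(1))
  copies <- sample(config$copies_per_prototype[1]:
                     config$copies_per_prototype[2], k, replace = TRUE)

  # per-prototype CNV truth
  type_draw <- runif(k)
  true_class <- ifelse(type_draw < config$cnv_prob, "CNV",
                       ifelse(type_draw < config$cnv_prob +
                                config$single_prob, "single_pair",
                              "constant"))
  ratios <- matrix(1, nrow = k, ncol = length(config$comparisons),
                   dimnames = list(NULL, config$comparisons))
  for (i in seq_len(k)) {
    if (true_class[i] == "CNV") {
      ratios[i, ] <- sample(config$copy_ratios, length(config$comparisons),
                            replace = TRUE)
    } else if (true_class[i] == "single_pair") {
      which_cmp <- sample(length(config$comparisons), 1)
      ratios[i, which_cmp] <- sample(config$copy_ratios, 1)
    }
  }

  # realize every copy
  copy_tbl <- tibble(
    prototype_id = rep(seq_len(k), times = copies)
  )
  copy_tbl <- copy_tbl[sample(nrow(copy_tbl)), , drop = FALSE]
  realized <- lapply(copy_tbl$prototype_id, function(pid) {
    m <- mutate_copy(protos[[pid]], config$substitution_rate,
                     config$indel_rate)
    rev <- runif(1) < config$reverse_prob
    seq <- if (rev) reverse_complement(m$seq) else m$seq
    list(seq = seq, strand = if (rev) "-" else "+",
         identity = 1 - (m$n_sub + m$n_indel) / proto_len[[pid]])
  })
  spacers <- sample(config$spacer_bp[1]:config$spacer_bp[2],
                    nrow(copy_tbl) + 1L, replace = TRUE)
  copy_len <- vapply(realized, function(x) nchar(x$seq), integer(1))
  content <- sum(copy_len) + sum(spacers)
  region_len <- config$region_len_bp
  if (is.null(region_len)) {
    region_len <- as.integer(ceiling(content * 1.15))
  } else if (region_len < content) {
    stop("region too small to place the planted copies: needs >= ", content)
  }

  pieces <- character(2 * nrow(copy_tbl) + 1)
  starts <- integer(nrow(copy_tbl))
  pos <- 0L
  extra <- region_len - content
  tail_bg <- extra %/% 2L
  head_bg <- extra - tail_bg
  pieces[1] <- rand_dna(spacers[1] + head_bg)
  pos <- spacers[1] + head_bg
  for (r in seq_len(nrow(copy_tbl))) {
    starts[r] <- pos
    pieces[2 * r] <- realized[[r]]$seq
    pos <- pos + copy_len[r]
    pieces[2 * r + 1] <- rand_dna(spacers[r + 1] +
                                    if (r == nrow(copy_tbl)) tail_bg else 0L)
    pos <- pos + spacers[r + 1] + if (r == nrow(copy_tbl)) tail_bg else 0L
  }
  genome <- paste(pieces, collapse = "")

  occurrences <- tibble(
    prototype_id = copy_tbl$prototype_id,
    start = starts,
    end = starts + copy_len,
    strand = vapply(realized, function(x) x$strand, character(1)),
    identity = vapply(realized, function(x) x$identity, numeric(1))
  ) |> dplyr::arrange(.data$start)

  prototypes <- tibble(
    prototype_id = seq_len(k),
    length_bp = proto_len,
    n_copies = copies,
    true_class = true_class,
    seq = unname(protos)
  )
  for (cmp in config$comparisons) {
    prototypes[[paste0("ratio_", cmp)]] <- ratios[, cmp]
    prototypes[[paste0("log2_", cmp)]] <- log2(ratios[, cmp])
  }

  structure(
    list(region = as_region(genome, name = "sim_region"),
         prototypes = prototypes, occurrences = occurrences,
         config = config),
    class = "sd_simulation"
  )
}

#' Generate an aCGH probe table matched to a simulation
#'
#' Plants `probes_per_element` probes per prototype inside randomly chosen
#' planted occurrences, then draws each probe's log2 ratio per comparison
#' and replicate from `Normal(log2(true copy ratio), probe_noise_sd)`.
#'
#' @param sim An `sd_simulation` from [simulate_sd_region()].
#' @param config Defaults to `sim$config`.
#' @return A probe tibble (see [read_probe_table()]) with an additional
#'   truth column `prototype_id`.
#' @export
simulate_acgh <- function(sim, config = sim$config) {
  set.seed(config$seed + 1L)
  rows <- list()
  for (pid in sim$prototypes$prototype_id) {
    occ <- dplyr::filter(sim$occurrences, .data$prototype_id == pid)
    npr <- config$probes_per_element
    plen <- sample(config$probe_len_bp[1]:config$probe_len_bp[2], npr,
                   replace = TRUE)
    oi <- sample(nrow(occ), npr, replace = TRUE)
    lo <- occ$start[oi]
    hi <- occ$end[oi] - plen
    pstart <- lo + floor(runif(npr) * pmax(1, hi - lo))
    probe <- tibble(
      probe_id = sprintf("p%02d_%04d", pid, seq_len(npr)),
      chrom = sim$region$chrom[[1]],
      start = as.integer(pstart),
      end = as.integer(pstart + plen),
      prototype_id = pid
    )
    for (cmp in config$comparisons) {
      mu <- sim$prototypes[[paste0("log2_", cmp)]][
        sim$prototypes$prototype_id == pid]
      for (repl in seq_len(config$n_replicates)) {
        rows[[length(rows) + 1L]] <- dplyr::mutate(
          probe, comparison = cmp, replicate = repl,
          log2_ratio = rnorm(npr, mean = mu, sd = config$probe_noise_sd)
        )
      }
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::select("probe_id", "chrom", "start", "end", "comparison",
                  "replicate", "log2_ratio", "prototype_id")
}

#' Write a simulation to a directory of plain-text fixtures
#'
#' Emits `genome.fa`, `truth_prototypes.fasta`, `truth_occurrences.bed`
#' (score = realized identity x 1000), `probes.tsv` and `config.txt` (the
#' resolved configuration).
#'
#' @param sim An `sd_simulation`.
#' @param dir Output directory (created if needed).
#' @param probes Optional probe table from [simulate_acgh()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, probes = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$region, file.path(dir, "genome.fa"))
  write_fasta(tibble(name = paste0("prototype_", sim$prototypes$prototype_id),
                     seq = sim$prototypes$seq),
              file.path(dir, "truth_prototypes.fasta"))
  write_bed(tibble(chrom = sim$region$chrom[[1]],
                   start = sim$occurrences$start,
                   end = sim$occurrences$end,
                   name = paste0("prototype_", sim$occurrences$prototype_id),
                   score = round(sim$occurrences$identity * 1000),
                   strand = sim$occurrences$strand),
            file.path(dir, "truth_occurrences.bed"))
  if (!is.null(probes)) {
    write_probe_table(probes, file.path(dir, "probes.tsv"))
  }
  cfg <- sim$config
  writeLines(paste0(names(cfg), " = ",
                    vapply(cfg, function(x) paste(x, collapse = ","),
                           character(1))),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' Match discovered cores to planted prototypes by occurrence overlap
#'
#' For evaluating a pipeline run against a simulation's truth: each core is
#' matched to the prototype whose planted occurrences overlap the most of
#' the core's mapped occurrences.
#'
#' @param occurrences Occurrence table from [map_core_occurrences()].
#' @param truth Truth occurrence table from [simulate_sd_region()]
#'   (`sim$occurrences`).
#' @return A tibble `(core_id, prototype_id, n_occurrences, n_truth)`.
#' @export
match_cores_to_truth <- function(occurrences, truth) {
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(occurrences$start + 1L, occurrences$end),
    IRanges::IRanges(truth$start + 1L, truth$end)
  )
  ov <- tibble(
    core_id = occurrences$core_id[S4Vectors::queryHits(hits)],
    prototype_id = truth$prototype_id[S4Vectors::subjectHits(hits)]
  )
  truth_n <- dplyr::count(truth, .data$prototype_id, name = "n_truth")
  occ_n <- dplyr::count(occurrences, .data$core_id, name = "n_occurrences")
  ov |>
    dplyr::count(.data$core_id, .data$prototype_id) |>
    dplyr::group_by(.data$core_id) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("core_id", "prototype_id") |>
    dplyr::left_join(occ_n, by = "core_id") |>
    dplyr::left_join(truth_n, by = "prototype_id")
}
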