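#' Keep repetitive sequences within a length window
#'
#' The fundamental-repetitive-sequence candidates are restricted to a length
#' window (default 3--4.5 kbp): long enough to be informative, short enough
#' that the survivors still cover most of the duplicated region.
#'
#' @param repseqs Repetitive-sequence tibble.
#' @param lo_bp,hi_bp Inclusive length bounds in bp.
#' @return The rows of `repseqs` with `lo_bp <= length_bp <= hi_bp`, order
#'   preserved.
#' @export
filter_by_length <- function(repseqs, lo_bp = 3000L, hi_bp = 4500L) {
  stopifnot(lo_bp <= hi_bp)
  dplyr::filter(repseqs, .data$length_bp >= lo_bp, .data$length_bp <= hi_bp)
}

#' Remove row/column-redundant repetitive sequences
#'
#' Greedy elimination on the self-plot geometry: the next surviving sequence
#' (longest first, ties by leftmost query then mate start) removes every
#' other sequence whose query or mate interval overlaps either of its own
#' footprints by more than `overlap_frac` of the shorter interval -- the
#' "same row or same column" rule. Repeats until no redundant sequence
#' remains. Deterministic given the ordering rule.
#'
#' @param repseqs Repetitive-sequence tibble with `qstart`, `qend`,
#'   `mstart`, `mend`.
#' @param overlap_frac Overlap tolerance as a fraction of the shorter
#'   interval.
#' @return The surviving rows (a tibble), with an `elimination_log`
#'   attribute: a tibble `(kept_id, removed_id)`.
#' @export
eliminate_redundant <- function(repseqs, overlap_frac = 0.5) {
  n <- nrow(repseqs)
  if (n == 0) {
    out <- repseqs
    attr(out, "elimination_log") <- tibble(kept_id = integer(),
                                           removed_id = integer())
    return(out)
  }
  ord <- order(-repseqs$length_bp, repseqs$qstart, repseqs$mstart)
  x <- repseqs[ord, , drop = FALSE]
  alive <- rep(TRUE, n)
  kept <- logical(n)
  log_kept <- integer(0)
  log_removed <- integer(0)

  band_overlap <- function(s1, e1, s2, e2) {
    ov <- pmin(e1, e2) - pmax(s1, s2)
    shorter <- pmin(e1 - s1, e2 - s2)
    ov > overlap_frac * shorter
  }
  repeat {
    cand <- which(alive & !kept)
    if (length(cand) == 0) break
    k <- cand[1]
    kept[k] <- TRUE
    others <- which(alive & !kept)
    if (length(others) == 0) next
    qs <- x$qstart[others]; qe <- x$qend[others]
    ms <- x$mstart[others]; me <- x$mend[others]
    conflict <-
      band_overlap(qs, qe, x$qstart[k], x$qend[k]) |
      band_overlap(qs, qe, x$mstart[k], x$mend[k]) |
      band_overlap(ms, me, x$qstart[k], x$qend[k]) |
      band_overlap(ms, me, x$mstart[k], x$mend[k])
    rm_idx <- others[conflict]
    if (length(rm_idx) > 0) {
      alive[rm_idx] <- FALSE
      log_kept <- c(log_kept, rep(x$id[k], length(rm_idx)))
      log_removed <- c(log_removed, x$id[rm_idx])
    }
  }
  out <- x[kept, , drop = FALSE]
  out <- out[order(out$qstart, out$mstart), , drop = FALSE]
  attr(out, "elimination_log") <- tibble(kept_id = log_kept,
                                         removed_id = log_removed)
  attr(out, "window_bp") <- attr(repseqs, "window_bp")
  out
}

#' Attach the query-footprint sequence of each repetitive sequence
#'
#' @param repseqs Tibble with `qstart`, `qend` (0-based half-open).
#' @param region One-row region tibble.
#' @return `repseqs` with a `seq` column (plus strand of the region).
#' @export
repseq_sequences <- function(repseqs, region) {
  seq <- region$seq[[1]]
  dplyr::mutate(repseqs,
                seq = stringr::str_sub(seq, .data$qstart + 1L, .data$qend))
}

#' Score all pairs of fundamental repetitive sequences
#'
#' Local alignment (BLASTN) of every unordered pair in both orientations;
#' the longest HSP per pair is kept. `shared_len_bp` is the number of
#' aligned columns and `identity` the fraction of identical columns within
#' them. Pairs with no alignment above the E-value cutoff score 0.
#'
#' @param fundamentals Tibble with `id` and `seq` columns (see
#'   [repseq_sequences()]).
#' @param config An [aligner_config()].
#' @return A tibble `(a, b, shared_len_bp, identity)` with `a < b`, one row
#'   per unordered pair.
#' @export
score_pairs <- function(fundamentals, config = aligner_config()) {
  ids <- fundamentals$id
  if (length(ids) < 2) {
    return(tibble(a = integer(), b = integer(), shared_len_bp = integer(),
                  identity = numeric()))
  }
  seqs <- setNames(fundamentals$seq, paste0("f", ids))
  hits <- run_blastn(seqs, seqs, config = config,
                     max_target_seqs = length(seqs) + 10L)
  hits <- hits |>
    dplyr::mutate(a = as.integer(sub("^f", "", .data$qseqid)),
                  b = as.integer(sub("^f", "", .data$sseqid))) |>
    dplyr::filter(.data$a != .data$b) |>
    dplyr::mutate(lo = pmin(.data$a, .data$b), hi = pmax(.data$a, .data$b)) |>
    dplyr::group_by(.data$lo, .data$hi) |>
    dplyr::arrange(dplyr::desc(.data$length), dplyr::desc(.data$bitscore),
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::transmute(a = .data$lo, b = .data$hi,
                     shared_len_bp = .data$length,
                     identity = .data$pident / 100)
  all_pairs <- as_tibble(t(combn(sort(ids), 2)), .name_repair = "minimal")
  names(all_pairs) <- c("a", "b")
  all_pairs |>
    dplyr::left_join(hits, by = c("a", "b")) |>
    dplyr::mutate(shared_len_bp = dplyr::coalesce(.data$shared_len_bp, 0L),
                  identity = dplyr::coalesce(.data$identity, 0))
}

#' Distribution of shared alignment lengths
#'
#' For each grid length `L`, the fraction of fundamental sequences sharing
#' an aligned region of at least `L` bp with at least one other fundamental
#' sequence. Non-increasing in `L`.
#'
#' @param scores Pair scores from [score_pairs()].
#' @param n_fundamentals Total number of fundamental sequences.
#' @param grid Numeric vector of shared-length thresholds (bp).
#' @return A tibble `(length, fraction)`.
#' @export
shared_length_distribution <- function(scores, n_fundamentals, grid) {
  if (length(grid) == 0) stop("empty grid")
  frac_at <- function(L) {
    sharing <- scores[scores$shared_len_bp >= L, c("a", "b")]
    length(unique(c(sharing$a, sharing$b))) / n_fundamentals
  }
  tibble(length = as.numeric(grid),
         fraction = vapply(grid, frac_at, numeric(1)))
}

#' Cluster fundamental sequences around representative sequences
#'
#' Greedy representative selection: among unassigned sequences, the one with
#' the most qualifying matches (shared length and identity above threshold)
#' to other unassigned sequences becomes the representative of a new group
#' (ties broken by lower id); everything matching it joins. Isolated
#' sequences form singleton groups. Groups partition the input and the
#' result is invariant to input order.
#'
#' @param scores Pair scores from [score_pairs()].
#' @param ids Ids of all fundamentals (defaults to those present in
#'   `scores`).
#' @param min_shared_bp Minimum shared alignment length for a qualifying
#'   match (default 2,700 bp).
#' @param min_identity Minimum alignment identity for a qualifying match.
#' @return A tibble `(group, member, representative, is_representative,
#'   match_count)`; `match_count` is the representative's qualifying-match
#'   count at formation time.
#' @export
cluster_fundamentals <- function(scores, ids = NULL, min_shared_bp = 2700L,
                                 min_identity = 0.7) {
  if (is.null(ids)) ids <- sort(unique(c(scores$a, scores$b)))
  ids <- sort(ids)
  q <- scores[scores$shared_len_bp >= min_shared_bp &
                scores$identity >= min_identity, c("a", "b")]
  adj <- lapply(setNames(vector("list", length(ids)), as.character(ids)),
                function(x) integer(0))
  for (r in seq_len(nrow(q))) {
    a <- as.character(q$a[r]); b <- as.character(q$b[r])
    adj[[a]] <- c(adj[[a]], q$b[r])
    adj[[b]] <- c(adj[[b]], q$a[r])
  }
  unassigned <- ids
  out <- list()
  g <- 0L
  while (length(unassigned) > 0) {
    cnt <- vapply(as.character(unassigned),
                  function(i) sum(adj[[i]] %in% unassigned), integer(1))
    rep_id <- unassigned[which.max(cnt)] # which.max: first max = lowest id
    members <- sort(c(rep_id,
                      intersect(adj[[as.character(rep_id)]], unassigned)))
    g <- g + 1L
    out[[g]] <- tibble(group = g, member = members, representative = rep_id,
                       is_representative = members == rep_id,
                       match_count = max(cnt))
    unassigned <- setdiff(unassigned, members)
  }
  dplyr::bind_rows(out)
}

complement_chars <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

#' Derive consensus core elements from clustered groups
#'
#' Star alignment of every group member to its representative (BLASTN local
#' alignments, both orientations, best-scoring alignment first at each
#' representative position), followed by a per-column majority consensus.
#' A representative column enters the consensus when more than
#' `majority_frac` of the members align across it; within such columns the
#' majority base is called when at least as many aligned members carry a
#' base as carry a gap, while columns where gaps predominate (insertions
#' private to the representative) are excised without interrupting the
#' consensus. Each maximal aligned block whose gap-free consensus is longer
#' than `min_len_bp` becomes one core element, so a group can yield one
#' core, two cores, or none (reported, not fatal). Tied majority columns
#' resolve alphabetically.
#'
#' @param groups Group table from [cluster_fundamentals()].
#' @param fundamentals Tibble with `id` and `seq` for every member.
#' @param min_len_bp Minimum core length (strictly greater; default 1,000).
#' @param majority_frac Fraction of members that must support a column
#'   (strictly greater; default 0.5).
#' @param config An [aligner_config()].
#' @return A tibble `(core_id, group, representative, n_members, length_bp,
#'   consensus)`; `core_id` is the representative id, suffixed `.1`, `.2`
#'   when a group yields several cores.
#' @export
derive_core_elements <- function(groups, fundamentals, min_len_bp = 1000L,
                                 majority_frac = 0.5,
                                 config = aligner_config()) {
  seq_of <- setNames(fundamentals$seq, as.character(fundamentals$id))
  res <- lapply(split(groups, groups$group), function(grp) {
    rep_id <- grp$representative[[1]]
    members <- grp$member
    rep_seq <- seq_of[[as.character(rep_id)]]
    L <- nchar(rep_seq)
    counts <- matrix(0L, nrow = 4, ncol = L,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    depth <- integer(L) # members whose alignment spans the column
    if (length(members) == 1) {
      bases <- stringr::str_split(rep_seq, "")[[1]]
      ok <- bases %in% rownames(counts)
      counts[cbind(match(bases[ok], rownames(counts)), which(ok))] <- 1L
      depth <- as.integer(ok)
    } else {
      mseqs <- setNames(seq_of[as.character(members)],
                        paste0("m", members))
      hits <- run_blastn(mseqs, setNames(rep_seq, "rep"), config = config,
                         fields = c(blast_fields, "qseq", "sseq"))
      hits <- dplyr::arrange(hits, .data$qseqid, dplyr::desc(.data$bitscore))
      for (m in unique(hits$qseqid)) {
        covered <- rep(FALSE, L)
        mh <- hits[hits$qseqid == m, , drop = FALSE]
        for (r in seq_len(nrow(mh))) {
          dir <- if (mh$send[r] >= mh$sstart[r]) 1L else -1L
          scol <- stringr::str_split(mh$sseq[r], "")[[1]]
          qcol <- stringr::str_split(mh$qseq[r], "")[[1]]
          nongap <- scol != "-"
          pos <- mh$sstart[r] + dir * (cumsum(nongap) - 1L)
          pos <- pos[nongap]
          base <- qcol[nongap]
          if (dir < 0) base <- unname(complement_chars[base])
          new_pos <- !covered[pos]
          covered[pos[new_pos]] <- TRUE
          depth[pos[new_pos]] <- depth[pos[new_pos]] + 1L
          keep <- base %in% rownames(counts) & new_pos
          if (any(keep)) {
            counts[cbind(match(base[keep], rownames(counts)), pos[keep])] <-
              counts[cbind(match(base[keep], rownames(counts)),
                           pos[keep])] + 1L
          }
        }
      }
    }
    with_base <- colSums(counts)
    aligned <- depth > majority_frac * length(members)
    has_base <- with_base >= depth - with_base & with_base > 0
    consensus <- rownames(counts)[apply(counts, 2, which.max)]
    # maximal aligned blocks; gap-majority columns inside a block are
    # excised, not breaks
    rl <- rle(aligned)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    blocks <- which(rl$values)
    seqs <- vapply(blocks, function(bk) {
      keep <- starts[bk]:ends[bk]
      paste(consensus[keep][has_base[keep]], collapse = "")
    }, character(1))
    ok <- nchar(seqs) > min_len_bp
    if (!any(ok)) {
      return(tibble(core_id = character(), group = integer(),
                    representative = integer(), n_members = integer(),
                    length_bp = integer(), consensus = character()))
    }
    seqs <- seqs[ok]
    tibble(
      core_id = if (length(seqs) == 1) as.character(rep_id)
                else paste0(rep_id, ".", seq_along(seqs)),
      group = grp$group[[1]],
      representative = rep_id,
      n_members = length(members),
      length_bp = nchar(seqs),
      consensus = seqs
    )
  })
  dplyr::bind_rows(res)
}

#' Map occurrences of core elements across the region
#'
#' BLASTN of each core consensus against both strands of the region. Hits
#' with identity at least `min_identity` spanning at least `min_cov_frac`
#' of the core are kept; overlapping same-strand hits of one core are
#' resolved by keeping the higher-identity hit (ties leftmost).
#'
#' @param cores Core-element table from [derive_core_elements()].
#' @param region One-row region tibble.
#' @param min_identity Minimum alignment identity (default 0.70).
#' @param min_cov_frac Minimum fraction of the core spanned by the hit.
#' @param config An [aligner_config()].
#' @return A tibble `(core_id, start, end, strand, identity, cov_frac)`
#'   sorted by position, 0-based half-open on the region.
#' @export
map_core_occurrences <- function(cores, region, min_identity = 0.70,
                                 min_cov_frac = 0.5,
                                 config = aligner_config()) {
  if (nrow(cores) == 0) {
    return(tibble(core_id = character(), start = integer(), end = integer(),
                  strand = character(), identity = numeric(),
                  cov_frac = numeric()))
  }
  qseqs <- setNames(cores$consensus, cores$core_id)
  hits <- run_blastn(qseqs, setNames(region$seq[[1]], region$name[[1]]),
                     config = config)
  core_len <- setNames(cores$length_bp, cores$core_id)
  occ <- hits |>
    dplyr::mutate(
      identity = .data$pident / 100,
      strand = ifelse(.data$send >= .data$sstart, "+", "-"),
      start = pmin(.data$sstart, .data$send) - 1L,
      end = pmax(.data$sstart, .data$send),
      cov_frac = (abs(.data$qend - .data$qstart) + 1) /
        core_len[.data$qseqid]
    ) |>
    dplyr::filter(.data$identity >= min_identity,
                  .data$cov_frac >= min_cov_frac) |>
    dplyr::transmute(core_id = .data$qseqid, start = .data$start,
                     end = .data$end, strand = .data$strand,
                     identity = .data$identity, cov_frac = .data$cov_frac)
  # resolve overlapping same-strand hits per core: higher identity wins
  occ <- occ |>
    dplyr::group_by(.data$core_id, .data$strand) |>
    dplyr::arrange(dplyr::desc(.data$identity), .data$start,
                   .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      keep <- logical(nrow(df))
      ks <- integer(0); ke <- integer(0)
      for (r in seq_len(nrow(df))) {
        if (!any(df$start[r] < ke & df$end[r] > ks)) {
          keep[r] <- TRUE
          ks <- c(ks, df$start[r]); ke <- c(ke, df$end[r])
        }
      }
      df[keep, , drop = FALSE]
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$start, .data$end, .data$core_id)
  occ
}

#' Fraction of the region covered by core-element occurrences
#'
#' @param occurrences Occurrence table from [map_core_occurrences()].
#' @param region_len Region length in bp.
#' @return A fraction in `[0, 1]`.
#' @export
region_coverage <- function(occurrences, region_len) {
  stopifnot(region_len > 0)
  interval_union_length(occurrences$start, occurrences$end) / region_len
}
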