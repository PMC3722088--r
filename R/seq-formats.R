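#' Read a FASTA file into a region table
#'
#' Each record becomes one row: a named sequence region with 0-based,
#' half-open coordinates covering the whole record (`start = 0`,
#' `end = nchar(seq)`). Lowercase bases are normalized to uppercase.
#'
#' @param path Path to a FASTA file.
#' @param on_illegal What to do with characters outside `A`, `C`, `G`, `T`,
#'   `N`: `"error"` rejects the file, `"mask"` replaces them with `N`.
#' @return A tibble with columns `name`, `chrom`, `start`, `end`, `length`
#'   and `seq`.
#' @export
read_fasta <- function(path, on_illegal = c("error", "mask")) {
  on_illegal <- match.arg(on_illegal)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("no FASTA records in ", path)
  seqs <- unname(toupper(as.character(ss)))
  if (any(nchar(seqs) == 0)) stop("empty FASTA record in ", path)
  bad <- stringr::str_detect(seqs, "[^ACGTN]")
  if (any(bad)) {
    if (on_illegal == "error") {
      stop("illegal characters (outside ACGTN) in record(s): ",
           paste(names(ss)[bad], collapse = ", "))
    }
    seqs <- stringr::str_replace_all(seqs, "[^ACGTN]", "N")
  }
  nm <- stringr::str_split_fixed(names(ss), "\\s+", 2)[, 1]
  tibble(
    name = nm, chrom = nm,
    start = 0L, end = nchar(seqs), length = nchar(seqs),
    seq = unname(seqs)
  )
}

#' Write a region table to FASTA
#'
#' @param regions Tibble with columns `name` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(regions, path) {
  ss <- Biostrings::DNAStringSet(setNames(regions$seq, regions$name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Build a one-row region table from a bare sequence
#'
#' @param seq DNA string over `A`, `C`, `G`, `T`, `N`.
#' @param name,chrom Labels for the region.
#' @return One-row tibble in the same shape as [read_fasta()].
#' @export
as_region <- function(seq, name = "region", chrom = name) {
  seq <- toupper(seq)
  if (stringr::str_detect(seq, "[^ACGTN]")) {
    stop("illegal characters in sequence (expected ACGTN)")
  }
  tibble(name = name, chrom = chrom, start = 0L, end = nchar(seq),
         length = nchar(seq), seq = seq)
}

#' Reverse complement of a DNA string
#'
#' `N` maps to `N`; the operation is an involution.
#'
#' @param seq DNA string over `A`, `C`, `G`, `T`, `N` (vectorized).
#' @return Character vector of reverse-complemented sequences.
#' @export
reverse_complement <- function(seq) {
  if (any(stringr::str_detect(seq, "[^ACGTNacgtn]"))) {
    stop("illegal characters in sequence (expected ACGTN)")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Read / write BED6 interval tables
#'
#' Plain 6-column BED: `chrom`, `start`, `end`, `name`, `score`, `strand`,
#' tab-separated, 0-based half-open, no header. The pair round-trips.
#'
#' @param intervals Tibble with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @param path File path.
#' @return `read_bed()` returns a tibble in the same shape; `write_bed()`
#'   returns `path` invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end", "name", "score", "strand")
                %in% names(intervals)))
  if (nrow(intervals) > 0 && any(intervals$start >= intervals$end)) {
    stop("invalid interval: start must be < end")
  }
  readr::write_tsv(
    intervals[, c("chrom", "start", "end", "name", "score", "strand")],
    path, col_names = FALSE
  )
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicdc", progress = FALSE
  )
  as_tibble(df)
}
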