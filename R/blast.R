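# Thin wrappers around command-line BLAST+ (blastn / makeblastdb), which
# backs the local-alignment steps: fundamental pair scoring, member-to-
# representative alignment for consensus building, and core-occurrence
# mapping. Scoring defaults follow a BLASTN-like scheme: match +1,
# mismatch -2, gap open 5, gap extend 2, no low-complexity filtering.

#' Local-alignment (BLASTN) configuration
#'
#' @param reward,penalty Match reward and mismatch penalty.
#' @param gapopen,gapextend Affine gap costs.
#' @param word_size Exact word size used to seed alignments.
#' @param evalue E-value cutoff.
#' @return A list of class `aligner_config`.
#' @export
aligner_config <- function(reward = 1L, penalty = -2L, gapopen = 5L,
                           gapextend = 2L, word_size = 11L, evalue = 1e-6) {
  structure(list(reward = reward, penalty = penalty, gapopen = gapopen,
                 gapextend = gapextend, word_size = word_size,
                 evalue = evalue),
            class = "aligner_config")
}

blast_available <- function() {
  nzchar(Sys.which("blastn"))
}

blast_args <- function(config) {
  c("-task", "blastn",
    "-reward", config$reward, "-penalty", config$penalty,
    "-gapopen", config$gapopen, "-gapextend", config$gapextend,
    "-word_size", config$word_size, "-evalue",
    format(config$evalue, scientific = TRUE),
    "-dust", "no", "-soft_masking", "false")
}

blast_fields <- c("qseqid", "sseqid", "pident", "length", "qstart", "qend",
                  "sstart", "send", "bitscore")

# Run blastn of named query sequences against named subject sequences.
# `fields` are outfmt 6 column names; qseq/sseq may be appended to recover
# the aligned strings. Uses makeblastdb when the subject has > 1 sequence.
run_blastn <- function(query, subject, config = aligner_config(),
                       fields = blast_fields, max_target_seqs = 5000L) {
  if (!blast_available()) {
    stop("blastn not found on the PATH; BLAST+ is required for this step")
  }
  td <- tempfile("blast")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  qf <- file.path(td, "query.fa")
  sf <- file.path(td, "subject.fa")
  write_fasta(tibble(name = names(query), seq = unname(query)), qf)
  write_fasta(tibble(name = names(subject), seq = unname(subject)), sf)
  args <- c("-query", qf, blast_args(config),
            "-outfmt", shQuote(paste(c("6", fields), collapse = " ")),
            "-max_target_seqs", max_target_seqs)
  if (length(subject) > 1) {
    db <- file.path(td, "db")
    out <- system2("makeblastdb",
                   c("-in", sf, "-dbtype", "nucl", "-out", db),
                   stdout = TRUE, stderr = TRUE)
    if (!is.null(attr(out, "status"))) {
      stop("makeblastdb failed: ", paste(out, collapse = "\n"))
    }
    args <- c(args, "-db", db)
  } else {
    args <- c(args, "-subject", sf)
  }
  res <- system2("blastn", args, stdout = TRUE, stderr = "")
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop("blastn failed with status ", status)
  }
  types <- c(qseqid = "c", sseqid = "c", pident = "d", length = "i",
             mismatch = "i", gaps = "i", qstart = "i", qend = "i",
             sstart = "i", send = "i", evalue = "d", bitscore = "d",
             sstrand = "c", qseq = "c", sseq = "c")
  if (length(res) == 0) {
    out <- lapply(fields, function(f) {
      switch(types[[f]], c = character(), i = integer(), d = numeric())
    })
    names(out) <- fields
    return(as_tibble(out))
  }
  df <- readr::read_tsv(I(paste(res, collapse = "\n")), col_names = fields,
                        col_types = paste(types[fields], collapse = ""),
                        progress = FALSE)
  as_tibble(df)
}
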