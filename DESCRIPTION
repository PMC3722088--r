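Package: repcore
Title: Core Repeat Elements and Copy Number Variation in Segmental Duplications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes large segmental duplications from a genomic region
    supplied as FASTA. Builds a windowed self-comparative dot-plot with a
    mismatch-tolerant seed criterion, extracts repetitive sequences as diagonal
    runs, distills them into nonredundant fundamental repetitive sequences,
    clusters them around representative sequences, derives gap-free consensus
    core elements, maps core-element occurrences across the region, and
    classifies each core element as CNV-type or constant-type from array-CGH
    probe log2 ratios using a one-sample t statistic with Bonferroni
    correction. Includes a synthetic-data generator that plants repeat
    prototypes and matched probe tables with known truth, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
SystemRequirements: NCBI BLAST+ (blastn, makeblastdb on the PATH)
Config/testthat/edition: 3
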