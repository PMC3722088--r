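test_that("seeded window matching equals the exhaustive Hamming oracle", {
  set.seed(21)
  for (mm in 0:2) {
    for (i in 1:15) {
      a <- random_dna(300)
      b <- random_dna(300)
      expect_identical(window_pair_matches(a, b, 30, mm),
                       oracle_seed_count(a, b, 30, mm))
      # near-identical pair: many matches
      b2 <- substitute_bases(a, 8)
      expect_identical(window_pair_matches(a, b2, 30, mm),
                       oracle_seed_count(a, b2, 30, mm))
    }
  }
})

test_that("identical windows match; reverse complement does not (forward)", {
  set.seed(22)
  a <- random_dna(300)
  expect_gte(window_pair_matches(a, a, 30, 2, cap = 1), 1)
  rc <- reverse_complement(a)
  expect_identical(window_pair_matches(a, rc, 30, 2),
                   oracle_seed_count(a, rc, 30, 2))
  expect_equal(window_pair_matches(a, rc, 30, 2), 0)
})

test_that("seeds containing N never match", {
  set.seed(23)
  a <- random_dna(300)
  an <- paste0(substr(a, 1, 100), strrep("N", 100), substr(a, 201, 300))
  expect_identical(window_pair_matches(a, an, 30, 2),
                   oracle_seed_count(a, an, 30, 2))
  expect_equal(window_pair_matches(strrep("N", 300), a, 30, 2), 0)
})

test_that("a planted duplication yields a 3-dot forward diagonal", {
  set.seed(24)
  bg <- strsplit(random_dna(6000), "")[[1]]
  dup <- strsplit(random_dna(900), "")[[1]]
  bg[601:1500] <- dup
  bg[3601:4500] <- dup
  region <- as_region(paste(bg, collapse = ""))
  dm <- build_self_dotplot(region, dotplot_config("fine"))
  fwd <- dm[dm$orientation == "+" & dm$i < dm$j, ]
  expect_true(all(paste(2:4, 12:14) %in% paste(fwd$i, fwd$j)))
  runs <- extract_diagonal_runs(dm)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$n_dots, 3)
  expect_equal(runs$orientation, "+")
  expect_equal(c(runs$qstart, runs$qend), c(600, 1500))
  expect_equal(c(runs$mstart, runs$mend), c(3600, 4500))
})

test_that("a reverse-oriented duplication yields an anti-diagonal run", {
  set.seed(25)
  bg <- strsplit(random_dna(6000), "")[[1]]
  dup <- random_dna(900)
  bg[601:1500] <- strsplit(dup, "")[[1]]
  bg[3601:4500] <- strsplit(reverse_complement(dup), "")[[1]]
  region <- as_region(paste(bg, collapse = ""))
  dm <- build_self_dotplot(region, dotplot_config("fine"))
  runs <- extract_diagonal_runs(dm)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$orientation, "-")
  expect_equal(runs$n_dots, 3)
  expect_equal(c(runs$qstart, runs$qend), c(600, 1500))
  expect_equal(c(runs$mstart, runs$mend), c(3600, 4500))
})

test_that("degenerate regions and masking behave as expected", {
  region_n <- as_region(strrep("N", 3000))
  expect_equal(nrow(build_self_dotplot(region_n, dotplot_config("fine"))), 0)

  set.seed(26)
  bg <- strsplit(random_dna(6000), "")[[1]]
  dup <- strsplit(random_dna(1200), "")[[1]]
  bg[601:1800] <- dup
  bg[3601:4800] <- dup
  full <- build_self_dotplot(as_region(paste(bg, collapse = "")),
                             dotplot_config("fine"))
  bg[3601:4800] <- "N" # mask one copy
  masked <- build_self_dotplot(as_region(paste(bg, collapse = "")),
                               dotplot_config("fine"))
  expect_lt(nrow(masked), nrow(full))

  expect_error(build_self_dotplot(as_region(random_dna(400)),
                                  dotplot_config("fine")),
               "shorter than two windows")
})

test_that("substitutions never increase the dot count", {
  set.seed(27)
  bg <- strsplit(random_dna(6000), "")[[1]]
  dup <- random_dna(1200)
  bg[601:1800] <- strsplit(dup, "")[[1]]
  prev <- Inf
  for (k in c(0, 30, 120, 400)) {
    copy <- if (k == 0) dup else substitute_bases(dup, k)
    bg[3601:4800] <- strsplit(copy, "")[[1]]
    dm <- build_self_dotplot(as_region(paste(bg, collapse = "")),
                             dotplot_config("fine"))
    expect_lte(nrow(dm), prev)
    prev <- nrow(dm)
  }
})

test_that("forward and reverse dots are stored symmetrically", {
  set.seed(28)
  bg <- strsplit(random_dna(9000), "")[[1]]
  dup <- random_dna(1200)
  bg[601:1800] <- strsplit(dup, "")[[1]]
  bg[3601:4800] <- strsplit(dup, "")[[1]]
  bg[6601:7800] <- strsplit(reverse_complement(dup), "")[[1]]
  dm <- build_self_dotplot(as_region(paste(bg, collapse = "")),
                           dotplot_config("fine"))
  key <- paste(dm$i, dm$j, dm$orientation)
  mirror <- paste(dm$j, dm$i, dm$orientation)
  expect_setequal(key, mirror)
  expect_true(any(dm$orientation == "-"))
})

test_that("dot plot agrees with per-pair window matching", {
  set.seed(29)
  bg <- strsplit(random_dna(4500), "")[[1]]
  dup <- random_dna(600)
  bg[301:900] <- strsplit(dup, "")[[1]]
  bg[2701:3300] <- strsplit(substitute_bases(dup, 12), "")[[1]]
  seq <- paste(bg, collapse = "")
  cfg <- dotplot_config("fine")
  dm <- build_self_dotplot(as_region(seq), cfg)
  n <- attr(dm, "n_windows")
  win <- function(i) substr(seq, i * 300 + 1, (i + 1) * 300)
  for (i in 0:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      if ((j - i) * 300 < cfg$min_offset_bp) next
      fwd <- window_pair_matches(win(i), win(j), 30, 2) >= 1
      rev <- window_pair_matches(win(i), reverse_complement(win(j)),
                                 30, 2) >= 1
      expect_equal(any(dm$i == i & dm$j == j & dm$orientation == "+"), fwd,
                   info = sprintf("fwd (%d,%d)", i, j))
      expect_equal(any(dm$i == i & dm$j == j & dm$orientation == "-"), rev,
                   info = sprintf("rev (%d,%d)", i, j))
    }
  }
})

test_that("dot matrices round-trip through TSV export", {
  set.seed(30)
  bg <- strsplit(random_dna(6000), "")[[1]]
  dup <- strsplit(random_dna(900), "")[[1]]
  bg[601:1500] <- dup
  bg[3601:4500] <- dup
  dm <- build_self_dotplot(as_region(paste(bg, collapse = "")),
                           dotplot_config("fine"))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_dots(dm, f)
  back <- read_dots(f)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(dm))
  expect_equal(attr(back, "n_windows"), attr(dm, "n_windows"))
  expect_equal(attr(back, "config")$window_bp, attr(dm, "config")$window_bp)

  empty <- make_dot_matrix(tibble::tibble(i = integer(), j = integer(),
                                          orientation = character()), 10L)
  export_dots(empty, f)
  expect_equal(nrow(read_dots(f)), 0)
})
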