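test_that("length filtering keeps the inclusive 3-4.5 kbp window", {
  reps <- tibble::tibble(id = 1:4, length_bp = c(900, 3000, 4500, 4800))
  kept <- filter_by_length(reps)
  expect_equal(kept$length_bp, c(3000, 4500))
  expect_equal(nrow(filter_by_length(reps[0, ])), 0)
  expect_equal(filter_by_length(kept), kept) # idempotent
})

test_that("row/column elimination is greedy and matches brute force", {
  # three copies of one repeat at loci A=[0,3000), B=[10000,13000),
  # C=[20000,23000): diagonal lines AB, AC, BC all conflict pairwise
  li <- function(id, q, m) {
    tibble::tibble(id = id, qstart = q, qend = q + 3000, mstart = m,
                   mend = m + 3000, strand = "+", n_dots = 10,
                   length_bp = 3000)
  }
  reps <- dplyr::bind_rows(li(1, 0, 10000), li(2, 0, 20000),
                           li(3, 10000, 20000))
  surv <- eliminate_redundant(reps)
  expect_equal(surv$id, 1) # longest-first, ties leftmost
  log <- attr(surv, "elimination_log")
  expect_setequal(log$removed_id, c(2, 3))
  expect_equal(unique(log$kept_id), 1)

  # brute force: any conflict-free set under the same rule has size 1
  conflicts <- function(a, b) {
    ov <- function(s1, e1, s2, e2) {
      pmin(e1, e2) - pmax(s1, s2) > 0.5 * pmin(e1 - s1, e2 - s2)
    }
    any(ov(c(a$qstart, a$qstart, a$mstart, a$mstart),
           c(a$qend, a$qend, a$mend, a$mend),
           c(b$qstart, b$mstart, b$qstart, b$mstart),
           c(b$qend, b$mend, b$qend, b$mend)))
  }
  sizes <- sapply(1:3, function(k) {
    sets <- combn(3, k, simplify = FALSE)
    any(sapply(sets, function(s) {
      prs <- if (length(s) < 2) list() else combn(s, 2, simplify = FALSE)
      all(sapply(prs, function(p) !conflicts(reps[p[1], ], reps[p[2], ])))
    }))
  })
  expect_equal(max(which(sizes)), nrow(surv))
})

test_that("non-conflicting repetitive sequences all survive", {
  li <- function(id, q, m) {
    tibble::tibble(id = id, qstart = q, qend = q + 3000, mstart = m,
                   mend = m + 3000, strand = "+", n_dots = 10,
                   length_bp = 3000)
  }
  reps <- dplyr::bind_rows(li(1, 0, 10000), li(2, 30000, 40000))
  surv <- eliminate_redundant(reps)
  expect_setequal(surv$id, c(1, 2))
  expect_equal(nrow(attr(surv, "elimination_log")), 0)

  single <- li(9, 5000, 50000)
  expect_equal(eliminate_redundant(single)$id, 9)
})

test_that("pair scores reflect identity, orientation and unrelatedness", {
  skip_if(!repcore:::blast_available(), "blastn not on PATH")
  set.seed(41)
  x <- random_dna(3000)
  y <- substitute_bases(x, 90) # ~97% identity
  z <- random_dna(3000)
  fund <- tibble::tibble(id = 1:4, seq = c(x, y, reverse_complement(x), z))
  sc <- score_pairs(fund)
  expect_equal(nrow(sc), 6)
  get <- function(a, b) sc[sc$a == a & sc$b == b, ]
  expect_gte(get(1, 2)$shared_len_bp, 2900)
  expect_gte(get(1, 2)$identity, 0.95)
  # reverse complement scores like the forward pair
  expect_equal(get(1, 3)$shared_len_bp, 3000)
  expect_equal(get(1, 3)$identity, 1)
  # unrelated random sequences share far less than the cluster threshold
  expect_lt(get(1, 4)$shared_len_bp, 2700)
  expect_lt(get(2, 4)$shared_len_bp, 2700)
})

test_that("identical sequences share their full length", {
  skip_if(!repcore:::blast_available(), "blastn not on PATH")
  set.seed(42)
  x <- random_dna(3000)
  fund <- tibble::tibble(id = 1:2, seq = c(x, x))
  sc <- score_pairs(fund)
  expect_equal(sc$shared_len_bp, 3000)
  expect_equal(sc$identity, 1)
})

test_that("shared-length distribution is a non-increasing fraction", {
  sc <- tibble::tibble(a = c(1, 1, 2), b = c(2, 3, 3),
                       shared_len_bp = c(3000, 1000, 2000),
                       identity = c(1, 1, 1))
  d <- shared_length_distribution(sc, 4, grid = c(500, 1500, 2500, 3500))
  expect_equal(d$fraction, c(3 / 4, 3 / 4, 2 / 4, 0))
  expect_true(all(diff(d$fraction) <= 0))
  none <- shared_length_distribution(sc[0, ], 4, grid = c(500, 1500))
  expect_equal(none$fraction, c(0, 0))
})

test_that("greedy clustering recovers planted groups and ignores order", {
  set.seed(43)
  x <- random_dna(3200)
  y <- random_dna(3200)
  fund_ids <- 1:9
  # qualifying matches: 1-5 are copies of x, 6-9 of y
  pairs <- expand.grid(a = fund_ids, b = fund_ids)
  pairs <- pairs[pairs$a < pairs$b, ]
  same <- (pairs$a <= 5 & pairs$b <= 5) | (pairs$a >= 6 & pairs$b >= 6)
  sc <- tibble::tibble(a = pairs$a, b = pairs$b,
                       shared_len_bp = ifelse(same, 3100L, 120L),
                       identity = ifelse(same, 0.97, 0.6))
  gr <- cluster_fundamentals(sc, ids = fund_ids)
  expect_equal(length(unique(gr$group)), 2)
  m1 <- sort(gr$member[gr$group == gr$group[gr$member == 1]])
  expect_equal(m1, 1:5)
  # representative has maximal match count; ties to lower id
  expect_equal(sort(unique(gr$representative)), c(1, 6))
  # invariance to score-row order
  gr2 <- cluster_fundamentals(sc[sample(nrow(sc)), ], ids = fund_ids)
  expect_equal(dplyr::arrange(gr2, member), dplyr::arrange(gr, member))
  # mutually unrelated input: all singletons
  sc0 <- dplyr::mutate(sc, shared_len_bp = 10L, identity = 0.3)
  gr0 <- cluster_fundamentals(sc0, ids = fund_ids)
  expect_equal(length(unique(gr0$group)), 9)
})

test_that("consensus of identical members reproduces the member", {
  skip_if(!repcore:::blast_available(), "blastn not on PATH")
  set.seed(44)
  x <- random_dna(3000)
  fund <- tibble::tibble(id = 1:5, seq = rep(x, 5))
  grp <- tibble::tibble(group = 1L, member = 1:5, representative = 1L,
                        is_representative = c(TRUE, rep(FALSE, 4)),
                        match_count = 4L)
  cores <- derive_core_elements(grp, fund)
  expect_equal(nrow(cores), 1)
  expect_equal(cores$consensus, x)
  expect_equal(cores$length_bp, 3000)
  expect_equal(cores$core_id, "1")
})

test_that("consensus of mutated members recovers the prototype", {
  skip_if(!repcore:::blast_available(), "blastn not on PATH")
  set.seed(45)
  proto <- random_dna(3200)
  member_seqs <- sapply(1:6, function(i) {
    repcore:::mutate_copy(proto, 0.02, 0.002)$seq
  })
  # mix orientations: members carry the copy as sliced from the plus strand
  member_seqs[c(2, 5)] <- reverse_complement(member_seqs[c(2, 5)])
  fund <- tibble::tibble(id = 1:6, seq = member_seqs)
  grp <- tibble::tibble(group = 1L, member = 1:6, representative = 1L,
                        is_representative = c(TRUE, rep(FALSE, 5)),
                        match_count = 5L)
  cores <- derive_core_elements(grp, fund)
  expect_equal(nrow(cores), 1)
  expect_gte(both_strand_identity(cores$consensus, proto), 99)
})

test_that("two conserved blocks split by spacers yield two cores", {
  skip_if(!repcore:::blast_available(), "blastn not on PATH")
  set.seed(46)
  block1 <- random_dna(1200)
  block2 <- random_dna(1300)
  mk <- function() paste0(block1, random_dna(500), block2)
  fund <- tibble::tibble(id = 1:4, seq = sapply(1:4, function(i) mk()))
  grp <- tibble::tibble(group = 1L, member = 1:4, representative = 1L,
                        is_representative = c(TRUE, rep(FALSE, 3)),
                        match_count = 3L)
  cores <- derive_core_elements(grp, fund, min_len_bp = 1000)
  expect_equal(nrow(cores), 2)
  expect_setequal(cores$core_id, c("1.1", "1.2"))
  ids <- sort(sapply(cores$consensus, function(cs) {
    max(both_strand_identity(cs, block1), both_strand_identity(cs, block2))
  }))
  expect_true(all(ids >= 99))
})

test_that("a group with only short shared blocks yields no core", {
  skip_if(!repcore:::blast_available(), "blastn not on PATH")
  set.seed(47)
  shared <- random_dna(800)
  fund <- tibble::tibble(id = 1:3, seq = sapply(1:3, function(i) {
    paste0(random_dna(1200), shared, random_dna(1200))
  }))
  grp <- tibble::tibble(group = 1L, member = 1:3, representative = 1L,
                        is_representative = c(TRUE, FALSE, FALSE),
                        match_count = 2L)
  cores <- derive_core_elements(grp, fund, min_len_bp = 1000)
  expect_equal(nrow(cores), 0)
})

test_that("occurrence mapping finds planted copies with correct strands", {
  skip_if(!repcore:::blast_available(), "blastn not on PATH")
  set.seed(48)
  core <- random_dna(1500)
  bg <- strsplit(random_dna(30000), "")[[1]]
  bg[2001:3500] <- strsplit(core, "")[[1]]
  bg[12001:13500] <- strsplit(core, "")[[1]]
  bg[22001:23500] <- strsplit(reverse_complement(core), "")[[1]]
  region <- as_region(paste(bg, collapse = ""))
  cores <- tibble::tibble(core_id = "c1", group = 1L, representative = 1L,
                          n_members = 3L, length_bp = 1500L,
                          consensus = core)
  occ <- map_core_occurrences(cores, region)
  expect_equal(nrow(occ), 3)
  expect_equal(occ$start, c(2000, 12000, 22000))
  expect_equal(occ$strand, c("+", "+", "-"))
  expect_equal(occ$identity, rep(1, 3))

  # a diverged copy is still found and reported near its true identity
  bg[12001:13500] <- strsplit(substitute_bases(core, 150), "")[[1]]
  occ2 <- map_core_occurrences(cores,
                               as_region(paste(bg, collapse = "")))
  mid <- occ2[occ2$start > 10000 & occ2$start < 14000, ]
  expect_equal(nrow(mid), 1)
  expect_gte(mid$identity, 0.85)
  expect_lt(mid$identity, 0.95)

  # absent core: no occurrences
  none <- map_core_occurrences(
    dplyr::mutate(cores, consensus = random_dna(1500)),
    as_region(random_dna(20000)))
  expect_equal(nrow(none), 0)
})

test_that("region coverage follows interval-union arithmetic", {
  occ <- tibble::tibble(core_id = "c", start = c(0, 500), end = c(1000, 1500),
                        strand = "+", identity = 1, cov_frac = 1)
  expect_equal(region_coverage(occ, 10000), 0.15)
  expect_equal(region_coverage(occ[0, ], 10000), 0)
  tile <- tibble::tibble(core_id = "c", start = seq(0, 9000, 1000),
                         end = seq(1000, 10000, 1000), strand = "+",
                         identity = 1, cov_frac = 1)
  expect_equal(region_coverage(tile, 10000), 1)
  # monotone under adding occurrences
  expect_gte(region_coverage(dplyr::bind_rows(occ, tile), 10000),
             region_coverage(occ, 10000))
})
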