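test_that("the t statistic handles degenerate and symmetric inputs", {
  r <- core_t_test(rep(0, 10))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_true(r$degenerate)

  r2 <- core_t_test(c(1, -1, 1, -1))
  expect_equal(r2$mean, 0)
  expect_equal(r2$t, 0)
  expect_equal(r2$p, 1)

  r3 <- core_t_test(rep(0.7, 5))
  expect_equal(r3$p, 0)
  expect_true(r3$degenerate)

  expect_error(core_t_test(0.5), "at least two")
})

test_that("the t statistic matches the textbook one-sample test", {
  set.seed(51)
  for (i in 1:200) {
    n <- sample(2:60, 1)
    v <- rnorm(n, mean = runif(1, -1, 1), sd = runif(1, 0.05, 2))
    r <- core_t_test(v)
    tt <- t.test(v, mu = 0)
    expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(r$p, tt$p.value, tolerance = 1e-12)
    expect_equal(r$n, n)
    expect_equal(r$var_unbiased, var(v))
    expect_equal(r$df, n - 1)
  }
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.001, 54), 0.054)
  expect_equal(bonferroni_adjust(0.5, 54), 1)
  expect_equal(bonferroni_adjust(0.3, 1), 0.3)
  expect_equal(bonferroni_adjust(c(0.001, 0.5), 54), c(0.054, 1))
  expect_error(bonferroni_adjust(1.2, 10), "outside")
})

test_that("classification follows the two-comparison decision rule", {
  expect_equal(classify_core(0.001, 0.002, 100, 100), "CNV")
  expect_equal(classify_core(0.3, 0.9, 100, 100), "constant")
  expect_equal(classify_core(0.001, 0.9, 100, 100), "single_pair")
  expect_equal(classify_core(0.001, 0.002, 25, 400), "insufficient")
  # symmetric in the two comparisons
  set.seed(52)
  for (i in 1:50) {
    pa <- runif(1)
    pb <- runif(1)
    na <- sample(c(10, 50, 200), 1)
    nb <- sample(c(10, 50, 200), 1)
    l1 <- classify_core(pa, pb, na, nb)
    l2 <- classify_core(pb, pa, nb, na)
    expect_equal(l1, l2)
  }
})

test_that("probes map to cores by midpoint containment", {
  occ <- tibble::tibble(core_id = c("a", "b", "b2"),
                        start = c(1000, 3000, 3500),
                        end = c(2000, 4000, 4500),
                        strand = "+", identity = 1, cov_frac = 1)
  probes <- tibble::tibble(
    probe_id = c("p1", "p2", "p3", "p4"),
    chrom = "r", start = c(1200, 2600, 3800, 9000),
    end = c(1260, 3060, 3860, 9060),
    comparison = "X_vs_Y", replicate = 1L,
    log2_ratio = c(0.5, 0.1, -0.2, 0)
  )
  m <- map_probes_to_cores(probes, occ)
  expect_setequal(m$probe_id[m$core_id == "a"], "p1")
  # p2 midpoint 2830 is outside every occurrence
  expect_false("p2" %in% m$probe_id)
  # p3 midpoint 3830 falls in overlapping occurrences of b and b2
  expect_setequal(m$core_id[m$probe_id == "p3"], c("b", "b2"))
  expect_false("p4" %in% m$probe_id)
})

test_that("planted probe assignment equals the truth table", {
  set.seed(53)
  occ <- tibble::tibble(core_id = c("c1", "c2"),
                        start = c(10000, 50000), end = c(14000, 54000),
                        strand = "+", identity = 1, cov_frac = 1)
  truth_core <- sample(c("c1", "c2"), 100, replace = TRUE)
  st <- ifelse(truth_core == "c1", 10000, 50000) +
    sample(0:3900, 100, replace = TRUE)
  probes <- tibble::tibble(probe_id = sprintf("p%03d", 1:100), chrom = "r",
                           start = st, end = st + 60,
                           comparison = "X_vs_Y", replicate = 1L,
                           log2_ratio = rnorm(100))
  m <- map_probes_to_cores(probes, occ)
  expect_equal(nrow(m), 100)
  expect_equal(m$core_id[match(probes$probe_id, m$probe_id)], truth_core)
})

test_that("core_cnv classifies planted shifts and pools replicates", {
  set.seed(54)
  occ <- tibble::tibble(core_id = c("cnv1", "flat1"),
                        start = c(0, 20000), end = c(4000, 24000),
                        strand = "+", identity = 1, cov_frac = 1)
  mk_probes <- function(core, mu_a, mu_b, n = 40) {
    st <- occ$start[occ$core_id == core] + sample(0:3900, n, replace = TRUE)
    base <- tibble::tibble(probe_id = paste0(core, "_", seq_len(n)),
                           chrom = "r", start = st, end = st + 60)
    dplyr::bind_rows(lapply(1:2, function(repl) {
      dplyr::bind_rows(
        dplyr::mutate(base, comparison = "A_vs_R", replicate = repl,
                      log2_ratio = rnorm(n, mu_a, 0.3)),
        dplyr::mutate(base, comparison = "B_vs_R", replicate = repl,
                      log2_ratio = rnorm(n, mu_b, 0.3))
      )
    }))
  }
  probes <- dplyr::bind_rows(mk_probes("cnv1", 1, 1), mk_probes("flat1", 0, 0))
  fit <- core_cnv(probes, occ, n_tests = 54)
  cls <- setNames(fit$classes$class, fit$classes$core_id)
  expect_equal(unname(cls["cnv1"]), "CNV")
  expect_equal(unname(cls["flat1"]), "constant")
  td <- tidy(fit)
  expect_setequal(names(td), c("core_id", "comparison", "n", "mean",
                               "var_unbiased", "t", "df", "p", "p_adj",
                               "degenerate", "class"))
  # replicates pooled: n equals the number of distinct probes
  expect_equal(unique(td$n), 40)
  g <- glance(fit)
  expect_equal(g$n_cores, 2)
  expect_equal(g$n_cnv, 1)
  expect_equal(g$n_constant, 1)

  # without pooling, both replicate measurements count
  fit2 <- core_cnv(probes, occ, pool_replicates = FALSE)
  expect_equal(unique(tidy(fit2)$n), 80)
})

test_that("cores below the probe floor are insufficient", {
  set.seed(55)
  occ <- tibble::tibble(core_id = "sparse", start = 0, end = 4000,
                        strand = "+", identity = 1, cov_frac = 1)
  st <- sample(0:3900, 25)
  probes <- dplyr::bind_rows(lapply(c("A_vs_R", "B_vs_R"), function(cmp) {
    tibble::tibble(probe_id = paste0("p", 1:25), chrom = "r", start = st,
                   end = st + 60, comparison = cmp, replicate = 1L,
                   log2_ratio = rnorm(25, 1, 0.3))
  }))
  fit <- core_cnv(probes, occ)
  expect_equal(fit$classes$class, "insufficient")
})

test_that("average log2 table sorts by the ordering comparison", {
  mapped <- tibble::tibble(
    core_id = rep(c("a", "b", "c", "d", "e"), each = 2),
    comparison = rep(c("X", "Y"), 5),
    probe_id = paste0("p", 1:10),
    log2_ratio = c(0.7, 0.1, 2, 0.2, 1, 1, -0.5, 0, 1.5, 0.3)
  )
  avg <- average_log2(mapped, order_by = "X")
  expect_equal(avg$core_id, c("b", "e", "c", "a", "d"))
  expect_equal(avg$X[avg$core_id == "a"], 0.7)
  single <- average_log2(
    tibble::tibble(core_id = "z", comparison = "X", probe_id = "p",
                   log2_ratio = 0.7), order_by = "X")
  expect_equal(single$X, 0.7)
})
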