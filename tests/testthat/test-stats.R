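test_that("all ICC variants match the aov-based oracle on toy matrices", {
  set.seed(71)
  for (r in 1:4) {
    mat <- matrix(rnorm(6, mean = 10), 3, 2)
    for (v in c("A1", "Ak", "C1", "Ck")) {
      expect_equal(icc_twoway(mat, v)$value, oracle_icc_aov(mat, v),
                   tolerance = 1e-12, label = paste("variant", v))
    }
  }
})

test_that("identical sessions give ICC 1 for every variant", {
  mat <- cbind(c(3, 7, 11, 5), c(3, 7, 11, 5), c(3, 7, 11, 5))
  for (v in c("A1", "Ak", "C1", "Ck")) {
    expect_equal(icc_twoway(mat, v)$value, 1, tolerance = 1e-12)
  }
})

test_that("incomplete session matrices are rejected", {
  mat <- cbind(c(1, 2, NA), c(2, 3, 4))
  expect_error(icc_twoway(mat), "imputation")
  expect_error(icc_twoway(matrix(1:2, 1, 2)), "2 subjects")
})

test_that("reference-cohort ICCs reproduce the published repeatability", {
  tab <- reference_tsc_table()
  vals <- vapply(c("GM", "TA", "S"), function(m) {
    icc_twoway(tsc_session_matrix(tab, m), "Ck")$value
  }, numeric(1))
  expect_equal(round(unname(vals), 3), c(0.784, 0.818, 0.807))
})

test_that("Bland-Altman limits behave for identical and normal data", {
  tab <- data.frame(subject = rep(1:5, 2),
                    session = rep(c("M1", "M2"), each = 5),
                    muscle = "GM",
                    tsc = rep(c(20, 19, 21, 20.5, 19.5), 2))
  ba <- bland_altman(tab, "GM", c("M1", "M2"))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_high - ba$loa_low, 0)
  # distributional oracle: limits converge to mu +/- 1.96 sigma
  set.seed(72)
  n <- 10000
  d <- rnorm(n, 0.3, 0.8)
  tab2 <- data.frame(subject = rep(seq_len(n), 2),
                     session = rep(c("M1", "M2"), each = n),
                     muscle = "GM",
                     tsc = c(10 + d, rep(10, n)))
  ba2 <- bland_altman(tab2, "GM", c("M1", "M2"))
  expect_equal(ba2$loa_low, 0.3 - 1.96 * 0.8, tolerance = 0.02 * 1.96 * 0.8)
  expect_equal(ba2$loa_high, 0.3 + 1.96 * 0.8, tolerance = 0.02 * 1.96 * 0.8)
  expect_gte(ba2$fraction_within, 0.90)
  expect_lte(ba2$fraction_within, 0.99)
  expect_error(bland_altman(tab[tab$subject < 3, ], "GM", c("M1", "M2")),
               "3 subjects")
})

test_that("Friedman statistic and p-values match closed forms", {
  # identical values: statistic 0, p 1 (midranks handle the ties)
  same <- matrix(5, 6, 3)
  fr0 <- friedman_test(same)
  expect_equal(fr0$statistic, 0)
  expect_equal(fr0$p_exact, 1)
  # perfect ordering for n = 10, k = 3: rank sums 30/20/10 -> statistic 20
  mat <- cbind(GM = 20 + 1:10 * 0.01, TA = 15 + 1:10 * 0.01,
               S = 10 + 1:10 * 0.01)
  fr <- friedman_test(mat)
  expect_equal(fr$statistic, 20)
  expect_lt(fr$p_exact, 0.001)
  # asymptotic branch agrees with stats::friedman.test (no ties)
  set.seed(73)
  m2 <- matrix(rnorm(30), 10, 3)
  fr2 <- friedman_test(m2)
  ref <- stats::friedman.test(m2)
  expect_equal(fr2$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(fr2$p_asymptotic, ref$p.value, tolerance = 1e-12)
})

test_that("exact Friedman p equals full enumeration for small n", {
  set.seed(74)
  for (r in 1:3) {
    mat <- matrix(rnorm(12), 4, 3)
    fr <- friedman_test(mat, mode = "exact")
    expect_equal(fr$p_exact, oracle_friedman_exact(mat), tolerance = 1e-12)
  }
  # with ties
  mat <- matrix(c(1, 1, 2, 3, 2, 2, 1, 3, 3, 3, 2, 1), 4, 3)
  expect_equal(friedman_test(mat, mode = "exact")$p_exact,
               oracle_friedman_exact(mat), tolerance = 1e-12)
})

test_that("signed-rank exact p matches 2^n enumeration for n <= 8", {
  set.seed(75)
  for (n in 4:8) {
    for (r in 1:3) {
      x <- rnorm(n, 0.4)
      y <- rnorm(n)
      got <- wilcoxon_signed_rank(x, y, mode = "exact")$p_exact
      expect_equal(got, oracle_signed_rank_exact(x, y), tolerance = 1e-12,
                   label = sprintf("n=%d rep=%d", n, r))
    }
  }
  # agreement with stats::wilcox.test exact p (continuous data, no ties)
  set.seed(79)
  x <- rnorm(9, 0.4)
  y <- rnorm(9)
  expect_equal(wilcoxon_signed_rank(x, y)$p_exact,
               stats::wilcox.test(x, y, paired = TRUE,
                                  exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("ten uniformly positive differences give p = 2/1024", {
  res <- wilcoxon_signed_rank(1:10 + 0.5, 1:10 - 0.5)
  expect_equal(res$statistic, 55)
  expect_equal(res$p_exact, 2 / 1024, tolerance = 1e-12)
  # Bonferroni multiplies and caps
  res3 <- wilcoxon_signed_rank(1:10 + 0.5, 1:10 - 0.5, m_comparisons = 3)
  expect_equal(res3$p, 3 * 2 / 1024, tolerance = 1e-12)
  expect_equal(res3$correction, "bonferroni")
  capped <- wilcoxon_signed_rank(c(1.2, 0.8), c(1, 1), m_comparisons = 3)
  expect_lte(capped$p, 1)
  # all-zero differences: p = 1
  expect_equal(wilcoxon_signed_rank(rep(2, 5), rep(2, 5))$p, 1)
})

test_that("exact and asymptotic signed-rank p agree for mid-range n = 10", {
  set.seed(76)
  ok <- 0
  for (r in 1:10) {
    x <- rnorm(10, 0.5)
    y <- rnorm(10)
    res <- wilcoxon_signed_rank(x, y)
    if (res$p_exact > 0.02 && res$p_exact < 0.9) {
      expect_lt(abs(res$p_asymptotic - res$p_exact) / res$p_exact, 0.2)
      ok <- ok + 1
    }
  }
  expect_gt(ok, 2)
})

test_that("rank-sum exact p matches enumeration for n <= 8", {
  set.seed(77)
  for (r in 1:6) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:4, 1)
    a <- rnorm(n1, 1)
    b <- rnorm(n2)
    got <- wilcoxon_rank_sum(a, b, mode = "exact")$p_exact
    expect_equal(got, oracle_rank_sum_exact(a, b), tolerance = 1e-12)
  }
  # with ties (midranks): still equals enumeration
  a <- c(1, 2, 2, 3)
  b <- c(2, 3, 4)
  expect_equal(wilcoxon_rank_sum(a, b, mode = "exact")$p_exact,
               oracle_rank_sum_exact(a, b), tolerance = 1e-12)
})

test_that("complete separation of 10 vs 5 gives p = 2/3003", {
  res <- wilcoxon_rank_sum(11:20, 1:5)
  expect_equal(res$p_exact, 2 / 3003, tolerance = 1e-12)
  expect_equal(round(res$p_exact, 4), 7e-04)
  # identical groups: p = 1 under the enumeration convention
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_exact, 1)
})

test_that("exact rank-sum p is consistent with permutation resampling", {
  set.seed(78)
  a <- rnorm(8, 0.8)
  b <- rnorm(7)
  res <- wilcoxon_rank_sum(a, b, mode = "exact")
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[1:8])
  ws <- replicate(50000, sum(sample(r, 8)))
  p_mc <- min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  expect_lt(abs(res$p_exact - p_mc), 0.015)
})

test_that("reference-table statistics reproduce the published findings", {
  tab <- reference_tsc_table()
  rep <- analyze_repeatability(tab)
  # muscles differ (printed P = 0.0005; asserted at the 0.05 level)
  expect_lt(rep$friedman$p_exact, 0.05)
  # healthy vs Addison separation per muscle (GM/S print as 0.0007)
  expect_equal(rep$group_comparison$GM$p_exact, 2 / 3003, tolerance = 1e-9)
  expect_equal(rep$group_comparison$S$p_exact, 2 / 3003, tolerance = 1e-9)
  expect_lt(rep$group_comparison$TA$p_exact, 0.05)
  # most Bland-Altman muscle/pair combinations have all points in limits
  frac <- vapply(rep$bland_altman, function(b) b$fraction_within,
                 numeric(1))
  expect_gt(mean(frac == 1), 0.5)
})
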