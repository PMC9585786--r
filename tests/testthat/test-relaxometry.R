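te20 <- c(0.4, 0.6, 1.0, 2.0, 5.0, 10.0, 12.0, 14.0, 16.0, 18.0, 20.0,
          22.0, 24.0, 26.0, 29.0, 32.0, 36.0, 40.0, 45.0, 50.0)
ti5 <- c(3, 15, 30, 60, 120)

roi_curve <- function(contrast, signal) {
  list(contrast_values = contrast, mean_signal = signal)
}

test_that("ROI extraction equals a brute-force voxel average", {
  set.seed(41)
  n <- 12
  vols <- lapply(1:4, function(i) array(rnorm(n^3, mean = 5), rep(n, 3)))
  mask <- array(FALSE, rep(n, 3))
  mask[3:7, 4:9, 2:11] <- TRUE
  roi <- extract_roi_series(vols, list(blob = mask), c(1, 2, 3, 4))
  brute <- vapply(vols, function(v) {
    s <- 0; cnt <- 0
    for (i in 1:n) for (j in 1:n) for (l in 1:n) {
      if (mask[i, j, l]) { s <- s + abs(v[i, j, l]); cnt <- cnt + 1 }
    }
    s / cnt
  }, numeric(1))
  expect_equal(roi$blob$mean_signal, brute, tolerance = 1e-12)
  expect_equal(roi$blob$n_voxels, sum(mask))
  # constant image: the mean is that constant at every contrast
  roiC <- extract_roi_series(lapply(1:3, function(i) {
    array(7, rep(n, 3))
  }), list(blob = mask), c(5, 1, 3))
  expect_equal(roiC$blob$mean_signal, rep(7, 3))
  # reference contrast defaults to the lowest TE (0.4 ms -> index 1)
  roiT <- extract_roi_series(lapply(te20, function(te) {
    array(exp(-te / 10), rep(n, 3))
  }), list(blob = mask), te20)
  expect_equal(roiT$blob$reference_contrast, 1L)
  expect_error(extract_roi_series(vols, list(empty = array(FALSE,
    rep(n, 3))), 1:4), "empty")
})

test_that("noiseless IR data recover T1 exactly", {
  si <- abs(8 * (1 - 2 * exp(-ti5 / 26))) + 0.3
  fit <- fit_t1_ir(roi_curve(ti5, si))
  expect_true(fit$converged)
  expect_lt(abs(fit$t1 - 26), 0.01)
  expect_equal(fit$mm, 8, tolerance = 1e-3)
  expect_equal(fit$offset, 0.3, tolerance = 1e-3)
})

test_that("T1 recovery is robust to 2% noise (Monte-Carlo study)", {
  set.seed(42)
  errs <- replicate(200, {
    si <- abs(8 * (1 - 2 * exp(-ti5 / 26))) + 0.3
    si <- si + rnorm(5, sd = 0.02 * max(si))
    fit_t1_ir(roi_curve(ti5, si))$t1
  })
  expect_lt(median(abs(errs - 26)) / 26, 0.05)
})

test_that("TI-independent signal is flagged degenerate", {
  fit <- fit_t1_ir(roi_curve(ti5, rep(4, 5)))
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_error(fit_t1_ir(roi_curve(c(3, 15, 30), c(1, 2, 3))), "4 distinct")
})

test_that("noiseless bi-exponential decay is recovered to 0.1%", {
  si <- 6 * exp(-te20 / 3.0) + 4 * exp(-te20 / 12.9) + 0.5
  fit <- fit_t2star(roi_curve(te20, si))
  expect_true(fit$converged)
  expect_lt(abs(fit$t2s - 3.0) / 3.0, 1e-3)
  expect_lt(abs(fit$t2l - 12.9) / 12.9, 1e-3)
  expect_lt(abs(fit$fs - 60) / 60, 1e-3)
  expect_equal(fit$fs + fit$fl, 100)
  expect_lte(fit$t2s, fit$t2l)
})

test_that("mono-exponential truth collapses the bi model", {
  si <- 10 * exp(-te20 / 12) + 0.2
  fit <- fit_t2star(roi_curve(te20, si))
  expect_true(fit$degenerate || fit$fl > 95 || fit$fs > 95)
  mono <- fit_t2star(roi_curve(te20, si), model = "mono")
  expect_lt(abs(mono$t2l - 12) / 12, 1e-3)
  expect_equal(mono$fl, 100)
})

test_that("the bi model never fits worse than the mono model", {
  set.seed(43)
  for (i in 1:5) {
    si <- 6 * exp(-te20 / runif(1, 2, 4)) + 4 * exp(-te20 / runif(1, 10, 15)) +
      0.3 + rnorm(20, sd = 0.05)
    bi <- fit_t2star(roi_curve(te20, si))
    mono <- fit_t2star(roi_curve(te20, si), model = "mono")
    expect_lte(bi$residual_rms, mono$residual_rms * (1 + 1e-6))
  }
})

test_that("cohort-truth recovery meets the per-parameter error budgets", {
  # 100 simulated ROIs with cohort-like parameter draws. T1 is identifiable
  # from 5 TIs already at curve SNR 30 (median < 5%). The bi-exponential
  # long component trades against the free offset and needs the effective
  # SNR of an ROI-mean curve from a high-SNR acquisition (~400 here) to
  # reach 5%; the short component is hardest and is budgeted at 15%.
  set.seed(44)
  e_t1 <- e_t2l <- e_t2s <- numeric(100)
  for (i in 1:100) {
    t1 <- runif(1, 24, 30)
    t2s <- runif(1, 2.5, 5.6)
    t2l <- runif(1, 11, 14)
    fs <- runif(1, 45, 60)
    s0 <- 10
    si_te <- s0 * ((fs / 100) * exp(-te20 / t2s) +
                   (1 - fs / 100) * exp(-te20 / t2l)) + 0.2
    si_te <- si_te + rnorm(20, sd = s0 / 400)
    ft2 <- fit_t2star(roi_curve(te20, pmax(si_te, 0)))
    si_ti <- abs(s0 * (1 - 2 * exp(-ti5 / t1))) + 0.2
    si_ti <- si_ti + rnorm(5, sd = s0 / 30)
    ft1 <- fit_t1_ir(roi_curve(ti5, pmax(si_ti, 0)))
    e_t1[i] <- abs(ft1$t1 - t1) / t1
    e_t2l[i] <- abs(ft2$t2l - t2l) / t2l
    e_t2s[i] <- abs(ft2$t2s - t2s) / t2s
  }
  expect_lt(median(e_t1), 0.05)
  expect_lt(median(e_t2l), 0.05)
  expect_lt(median(e_t2s), 0.15)
})

test_that("relaxometry_table collects per-muscle fits", {
  rois <- list(
    GM = roi_curve(te20, 6 * exp(-te20 / 3.6) + 4 * exp(-te20 / 12.9) + 0.1),
    TA = roi_curve(te20, 6 * exp(-te20 / 3.2) + 4 * exp(-te20 / 12.8) + 0.1))
  tab <- relaxometry_table(rois, "t2star")
  expect_equal(tab$muscle, c("GM", "TA"))
  expect_equal(tab$t2s, c(3.6, 3.2), tolerance = 1e-3)
  rois_t1 <- list(GM = roi_curve(ti5, abs(5 * (1 - 2 * exp(-ti5 / 25.9)))))
  tab1 <- relaxometry_table(rois_t1, "t1")
  expect_equal(tab1$t1, 25.9, tolerance = 1e-3)
})
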