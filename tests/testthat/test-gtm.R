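gauss_kernel3 <- function(n, fwhm_vox) {
  xs <- (seq_len(n) - 1 - floor(n / 2))
  s <- fwhm_vox / 2.355
  g1 <- exp(-xs^2 / (2 * s^2))
  k <- outer(outer(g1, g1), g1)
  k / sum(k)
}

test_that("a delta kernel leaves masks and GTM untouched", {
  n <- 16
  delta <- array(0, rep(n, 3))
  delta[n / 2 + 1, n / 2 + 1, n / 2 + 1] <- 1
  mask <- array(FALSE, rep(n, 3))
  mask[4:8, 6:10, 5:9] <- TRUE
  expect_equal(compute_rsf(mask, delta), mask + 0, tolerance = 1e-12)
  masks <- list(a = mask, b = !mask)
  img <- 3 * mask + 1.5 * !mask
  g <- gtm_correct(masks, delta, img)
  expect_equal(unname(g$weights), diag(2), tolerance = 1e-12)
  expect_equal(unname(g$solved), unname(g$observed), tolerance = 1e-12)
})

test_that("circular convolution preserves the mask mass exactly", {
  n <- 16
  mask <- array(FALSE, rep(n, 3))
  mask[3:10, 2:12, 4:11] <- TRUE
  k <- gauss_kernel3(16, 2)
  rsf <- compute_rsf(mask, k, circular = TRUE)
  expect_lt(abs(sum(rsf) - sum(mask)) / sum(mask), 1e-9)
})

test_that("RSFs match a brute-force spatial convolution loop", {
  n <- 16
  mask <- array(FALSE, rep(n, 3))
  mask[6:10, 4:12, 7:9] <- TRUE
  k <- gauss_kernel3(5, 1.5)
  rsf <- compute_rsf(mask, k)
  expect_lt(max(abs(rsf - oracle_conv3(mask, k))), 1e-8)
})

test_that("an unnormalized kernel is normalized with a notice", {
  n <- 16
  mask <- array(FALSE, rep(n, 3))
  mask[5:9, 5:9, 5:9] <- TRUE
  k <- gauss_kernel3(5, 1.5) * 3
  expect_message(rsf <- compute_rsf(mask, k), "normaliz")
  expect_lt(abs(sum(rsf) - sum(mask)) / sum(mask), 1e-6)
})

test_that("GTM inverts a Gaussian blur of a piecewise-constant phantom", {
  n <- 32
  ph <- make_digital_phantom(n, "healthy")
  masks <- phantom_masks(ph, c("GM", "TA", "S", "other", "background"))
  truth <- c(19.9, 13.8, 12.6, 15.0, 0)
  img <- phantom_param_map(ph, "tsc")
  img[ph$labels > 4] <- 0                 # tubes excluded from this toy
  k <- gauss_kernel3(n, 2)
  blurred <- compute_rsf(img, k, circular = TRUE)
  g <- gtm_correct(masks, k, blurred, circular = TRUE)
  expect_lt(max(abs(g$solved[1:4] - truth[1:4]) / truth[1:4]), 0.005)
  # observed means are biased; the solve removes the bias
  expect_gt(max(abs(g$observed[1:4] - truth[1:4]) / truth[1:4]), 0.02)
})

test_that("GTM with the imaging operator is exact including the tubes", {
  n <- 32
  ph <- make_digital_phantom(n, "healthy")
  tr <- refine_density_weights(
    build_da3dpr_trajectory(1500, n, 160 / n), iterations = 8)
  op <- psf_operator(tr, n)
  masks <- phantom_masks(ph, c("GM", "TA", "S", "other"))
  for (k in 1:4) masks[[paste0("tube", k)]] <- ph$labels == 4L + k
  img <- Mod(op(phantom_param_map(ph, "tsc")))
  g <- gtm_correct(masks, op, img)
  truth <- c(19.9, 13.8, 12.6, 15.0, 15.4, 30.8, 46.2, 61.6)
  expect_lt(max(abs(g$solved - truth) / truth), 0.01)
})

test_that("solution error grows monotonically with noise", {
  set.seed(51)
  n <- 24
  ph <- make_digital_phantom(32, "healthy")
  # use a 32-grid phantom blurred by a Gaussian, with increasing noise
  masks <- phantom_masks(ph, c("GM", "TA", "S", "other", "background"))
  img <- phantom_param_map(ph, "tsc")
  img[ph$labels > 4] <- 0
  k <- gauss_kernel3(32, 2)
  blurred <- compute_rsf(img, k, circular = TRUE)
  truth <- c(19.9, 13.8, 12.6, 15.0, 0)
  err <- vapply(c(0, 0.5, 2), function(s) {
    e <- numeric(6)
    for (r in 1:6) {
      noisy <- blurred + array(rnorm(length(blurred), sd = s), dim(blurred))
      g <- gtm_correct(masks, k, noisy, circular = TRUE)
      e[r] <- mean(abs(g$solved[1:3] - truth[1:3]))
    }
    mean(e)
  }, numeric(1))
  expect_true(all(diff(err) > 0))
})

test_that("ill-conditioned systems are rejected with advice", {
  n <- 16
  mask <- array(FALSE, rep(n, 3))
  mask[6:10, 6:10, 6:10] <- TRUE
  shifted <- array(FALSE, rep(n, 3))
  shifted[7:11, 6:10, 6:10] <- TRUE
  # huge blur makes two interleaved compartments indistinguishable
  k <- gauss_kernel3(n, 12)
  masks <- list(a = mask & !shifted, b = shifted & !mask)
  img <- array(1, rep(n, 3))
  expect_error(gtm_correct(masks, k, img, circular = TRUE,
                           max_condition = 1.01), "merg")
})

test_that("GTM audit dump round-trips through CSV", {
  n <- 16
  delta <- array(0, rep(n, 3))
  delta[n / 2 + 1, n / 2 + 1, n / 2 + 1] <- 1
  mask <- array(FALSE, rep(n, 3))
  mask[4:8, 6:10, 5:9] <- TRUE
  g <- gtm_correct(list(a = mask, b = !mask), delta, 2 * mask + 1 * !mask)
  path <- tempfile(fileext = ".csv")
  write_gtm_csv(g, path)
  df <- read.csv(path)
  expect_equal(df$solved, unname(g$solved), tolerance = 1e-9)
  unlink(path)
})
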