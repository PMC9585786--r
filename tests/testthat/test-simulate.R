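# Shared small-scale phantom/protocol for the simulator tests.
ph32 <- make_digital_phantom(32, "healthy", n_coils = 1)
prot32 <- protocol_preset("t2star", matrix = 32, n_projections = 1500)
traj32 <- refine_density_weights(
  build_da3dpr_trajectory(1500, 32, 160 / 32), iterations = 8)
psf32 <- simulate_psf(traj32, 32, method = "gridding",
                      t2s = 3.3, t2l = 12.9, fs = 60)

test_that("noiseless multi-echo series decays monotonically per voxel", {
  acq <- simulate_series(ph32, prot32, noise_sigma = 0, psf = psf32,
                         traj = traj32)
  masks <- phantom_masks(ph32, c("GM", "TA", "S"))
  vols <- lapply(seq_along(acq$contrast_values),
                 function(ci) acq$volumes[[ci]][[1]])
  roi <- extract_roi_series(vols, masks, acq$contrast_values)
  for (nm in names(roi)) {
    expect_true(all(diff(roi[[nm]]$mean_signal) < 0))
  }
  # noiseless volumes are exact linear combinations of the basis: the first
  # echo is strictly brighter than the last everywhere in muscle
  m <- ph32$labels %in% 1:4
  expect_true(all(Mod(vols[[1]])[m] > Mod(vols[[20]])[m]))
})

test_that("signed IR model crosses zero at TI = T1 ln 2", {
  expect_equal(ir_signal(10, t1 = 26, t2s = 3, t2l = 13, fs = 60,
                         ti = 26 * log(2), te = 0.5), 0, tolerance = 1e-12)
  ti <- c(3, 15, 30, 60, 120)
  s <- ir_signal(10, 26, 3, 13, 60, ti = ti, te = 0.5)
  expect_true(all(s[ti < 26 * log(2)] < 0))
  expect_true(all(s[ti > 26 * log(2)] > 0))
})

test_that("same seed reproduces the series bitwise; seeds differ", {
  a1 <- simulate_series(ph32, prot32, seed = 5, psf = psf32, traj = traj32)
  a2 <- simulate_series(ph32, prot32, seed = 5, psf = psf32, traj = traj32)
  a3 <- simulate_series(ph32, prot32, seed = 6, psf = psf32, traj = traj32)
  expect_identical(a1$volumes, a2$volumes)
  expect_false(identical(a1$volumes, a3$volumes))
  expect_identical(a1$noise_only, a2$noise_only)
})

test_that("noise calibration hits the target object SNR", {
  prot_na <- protocol_preset("sodium", matrix = 32, n_projections = 1500)
  acq <- simulate_series(ph32, prot_na, seed = 9, target_snr = 16,
                         psf = psf32, traj = traj32)
  snr <- multiple_replica_snr(acq, n_replicas = 60, seed = 10)
  m <- ph32$labels %in% 1:4
  expect_equal(mean(snr$snr[m]), 16, tolerance = 0.15 * 16)
})

test_that("noise-only volumes have zero-mean complex noise", {
  acq <- simulate_series(ph32, prot32, seed = 7, psf = psf32, traj = traj32)
  nv <- acq$noise_only[[1]][[1]]
  expect_gt(acq$noise_sigma, 0)
  expect_equal(mean(Re(nv)), 0, tolerance = 4 * acq$noise_sigma /
                 sqrt(length(nv)))
  expect_equal(sd(Re(nv)), acq$noise_sigma, tolerance = 0.05 *
                 acq$noise_sigma)
})

test_that("PSF-basis mode and k-space mode agree on noiseless phantoms", {
  prot_na <- protocol_preset("sodium", matrix = 32, n_projections = 1500)
  a_img <- simulate_series(ph32, prot_na, mode = "image_psf",
                           noise_sigma = 0, psf = psf32, traj = traj32)
  a_ksp <- simulate_series(ph32, prot_na, mode = "kspace",
                           noise_sigma = 0, traj = traj32)
  v1 <- Mod(a_img$volumes[[1]][[1]])
  v2 <- Mod(a_ksp$volumes[[1]][[1]])
  sc <- sum(v1 * v2) / sum(v2^2)
  expect_lt(sqrt(mean((v1 - sc * v2)^2)) / sqrt(mean(v1^2)), 0.03)
})

test_that("unphysical contrast times are rejected", {
  bad <- prot32
  bad$te_list <- c(0.4, 2e4)
  bad$tr <- 3e4
  expect_error(simulate_series(ph32, bad, psf = psf32, traj = traj32),
               "physical range")
})

test_that("series export writes one NIfTI per contrast plus a sidecar", {
  prot_short <- protocol_preset("b0_map", matrix = 32,
                                n_projections = 1500)
  acq <- simulate_series(ph32, prot_short, seed = 3, psf = psf32,
                         traj = traj32)
  prefix <- file.path(tempdir(), "series_test")
  paths <- write_series_nifti(acq, prefix)
  expect_length(paths, length(acq$contrast_values) + 1)
  expect_true(all(file.exists(paths)))
  unlink(paths)
})
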