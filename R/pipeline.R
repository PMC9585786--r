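# End-to-end orchestration: simulate -> reconstruct/correct -> relaxometry
# -> GTM -> calibrate -> TSC -> repeatability statistics.

#' Default pipeline configuration
#'
#' @param matrix simulation matrix size (default 64; the acquisition-scale
#'   128 is available but slower).
#' @param scenario phantom scenario (\code{"healthy"} or \code{"addison"}).
#' @param seed master seed; stage seeds are derived by small offsets.
#' @param target_snr muscle SNR the sodium acquisition is calibrated to
#'   (default 16).
#' @param mode forward-simulation mode (\code{"image_psf"} or
#'   \code{"kspace"}).
#' @param corrections named logical list toggling the intensity/B1
#'   correction (\code{b1}), off-resonance handling (\code{b0}),
#'   partial-volume correction (\code{pve}) and relaxation-difference
#'   correction (\code{relaxation}).
#' @param run_relaxometry simulate the multi-echo and inversion-recovery
#'   series and fit relaxation times (default TRUE).
#' @param n_coils number of receive channels.
#' @param snr_replicas replicas for the SNR map.
#' @param tube_margin_mm erosion margin of the calibration-tube ROIs.
#' @return named list of configuration values.
#' @export
default_config <- function(matrix = 64, scenario = "healthy",
                           seed = 20220719, target_snr = 16,
                           mode = "image_psf",
                           corrections = list(b0 = TRUE, b1 = TRUE,
                                              pve = TRUE, relaxation = TRUE),
                           run_relaxometry = TRUE, n_coils = 2,
                           snr_replicas = 50, tube_margin_mm = 5) {
  list(matrix = matrix, fov = 160, scenario = scenario, seed = seed,
       target_snr = target_snr, mode = mode, corrections = corrections,
       run_relaxometry = run_relaxometry, n_coils = n_coils,
       snr_replicas = snr_replicas, tube_margin_mm = tube_margin_mm)
}

# Root-sum-of-squares magnitude combination (cheap path for long series).
rss_magnitude <- function(coils) {
  sqrt(Reduce(`+`, lapply(coils, function(v) Mod(v)^2)))
}

# Dual-echo B0-mapping acquisition pair on a phantom: complex volumes whose
# inter-echo phase carries the phantom's B0 map.
simulate_b0_pair <- function(ph, prot, noise_sigma = 0, seed = 1) {
  tab <- ph$label_table
  lvl1 <- steady_state_signal(tab$tsc, tab$t1, tab$t2s, tab$t2l, tab$fs,
                              tr = prot$tr[1], te = prot$te_list[1])
  lvl2 <- steady_state_signal(tab$tsc, tab$t1, tab$t2s, tab$t2l, tab$fs,
                              tr = prot$tr[1], te = prot$te_list[2])
  shade <- sin(prot$flip_nominal * ph$b1_map * pi / 180)
  m1 <- array(lvl1[match(ph$labels, tab$label)], dim = dim(ph$labels)) * shade
  m2 <- array(lvl2[match(ph$labels, tab$label)], dim = dim(ph$labels)) * shade
  e1 <- m1 * exp(2i * pi * ph$b0_map * prot$te_list[1] * 1e-3)
  e2 <- m2 * exp(2i * pi * ph$b0_map * prot$te_list[2] * 1e-3)
  if (noise_sigma > 0) {
    with_seed(seed, {
      e1 <- e1 + complex_noise(dim(e1), noise_sigma)
      e2 <- e2 + complex_noise(dim(e2), noise_sigma)
    })
  }
  list(echo1 = e1, echo2 = e2)
}

#' Run the full quantification pipeline on a synthetic calf
#'
#' Simulates the sodium acquisition of the requested scenario plus the
#' homogeneous-cylinder calibration scan, estimates SNR and B0/B1 maps,
#' applies the cylinder-derived intensity correction, performs GTM
#' partial-volume correction of the muscle compartment means, builds the
#' tube calibration curve and computes TSC — alongside an uncorrected TSC
#' estimate for ablation comparison, and (optionally) full relaxometry.
#'
#' @param config configuration list from \code{\link{default_config}}.
#' @return object of class \code{pipeline_result}; key fields:
#'   \code{tsc} and \code{tsc_uncorrected} (data.frames with truth and
#'   recovery errors), \code{snr_muscle}, \code{gtm}, \code{calibration},
#'   \code{fieldmaps} (estimated vs true B0/B1 summaries),
#'   \code{relaxometry} (fit tables), \code{config}.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- config
  t_start <- Sys.time()
  n_proj <- if (is.null(cfg$n_projections)) 5000 else cfg$n_projections
  prot <- protocol_preset("sodium", matrix = cfg$matrix, fov = cfg$fov,
                          n_projections = n_proj)

  ph <- make_digital_phantom(cfg$matrix, cfg$scenario, seed = cfg$seed,
                             fov = cfg$fov, n_coils = cfg$n_coils)
  cyl <- make_digital_phantom(cfg$matrix, "cylinder", seed = cfg$seed + 1,
                              fov = cfg$fov, n_coils = cfg$n_coils)

  traj <- refine_density_weights(protocol_trajectory(prot))
  psf <- simulate_psf(traj, cfg$matrix, method = "gridding",
                      t2s = .COHORT_DECAY$t2s, t2l = .COHORT_DECAY$t2l,
                      fs = .COHORT_DECAY$fs)
  op <- psf_operator(traj, cfg$matrix, t2s = .COHORT_DECAY$t2s,
                     t2l = .COHORT_DECAY$t2l, fs = .COHORT_DECAY$fs)

  acq <- simulate_series(ph, prot, mode = cfg$mode, seed = cfg$seed + 2,
                         target_snr = cfg$target_snr, psf = psf,
                         traj = traj)
  acq_cyl <- simulate_series(cyl, prot, mode = cfg$mode,
                             seed = cfg$seed + 3,
                             noise_sigma = acq$noise_sigma, psf = psf,
                             traj = traj)

  combined <- combined_magnitude(acq, 1)
  combined_cyl <- combined_magnitude(acq_cyl, 1)

  snr_map <- multiple_replica_snr(acq, n_replicas = cfg$snr_replicas,
                                  seed = cfg$seed + 4)
  muscle_mask <- ph$labels %in% 1:4
  snr_muscle <- mean(snr_map$snr[muscle_mask])

  # field maps estimated from the cylinder (transferred to the subject scan)
  prot_b0 <- protocol_preset("b0_map", matrix = cfg$matrix, fov = cfg$fov)
  b0_pair <- simulate_b0_pair(cyl, prot_b0,
                              noise_sigma = 0.02 * max(combined_cyl),
                              seed = cfg$seed + 5)
  b0_est <- b0_map_dual_echo(b0_pair$echo1, b0_pair$echo2,
                             prot_b0$te_list[1], prot_b0$te_list[2])
  prot_b1 <- protocol_preset("b1_map", matrix = cfg$matrix, fov = cfg$fov)
  b1_pair <- simulate_b1_pair(cyl, prot_b1)
  b1_est <- b1_map_phase_sensitive(b1_pair$prepared, b1_pair$reference,
                                   prot_b1$flip_nominal)
  sup <- b0_est$support_mask & b1_est$support_mask
  fieldmaps <- list(
    b0_rmse = sqrt(mean((b0_est$b0[sup] - cyl$b0_map[sup])^2)),
    b1_rmse = sqrt(mean((b1_est$b1[sup] - cyl$b1_map[sup])^2,
                        na.rm = TRUE)),
    b0 = b0_est, b1 = b1_est)

  # intensity correction from the homogeneous cylinder
  if (isTRUE(cfg$corrections$b1)) {
    corr <- derive_and_apply_correction(combined, combined_cyl)
    corrected <- corr$corrected
  } else {
    corr <- NULL
    corrected <- combined
  }

  # GTM compartments: muscles, surrounding muscle, and the calibration
  # tubes (bright, so they must be modeled even though their own means are
  # read directly from eroded ROIs). The zero-concentration background
  # contributes nothing and is left out of the system: modeling it would
  # feed rectified noise/ringing magnitudes into the solve.
  masks <- phantom_masks(ph, c("GM", "TA", "S", "other"))
  for (k in 1:4) masks[[paste0("tube", k)]] <- ph$labels == 4L + k
  muscles <- c("GM", "TA", "S")

  # calibration tubes (eroded interior ROIs; tubes bypass the GTM)
  tube_rois <- calibration_tube_rois(ph, margin_mm = cfg$tube_margin_mm)
  tube_means_corr <- vapply(tube_rois, function(m) mean(corrected[m]),
                            numeric(1))
  tube_means_raw <- vapply(tube_rois, function(m) mean(combined[m]),
                           numeric(1))

  tissue_relax <- cohort_relaxation_defaults()
  phantom_relax <- phantom_relaxation_defaults()
  if (!isTRUE(cfg$corrections$relaxation)) {
    # disable relaxation-difference correction: use phantom factors for all
    tissue_relax$t1 <- phantom_relax$t1
    tissue_relax$t2s <- phantom_relax$t2s
    tissue_relax$t2l <- phantom_relax$t2l
    tissue_relax$fs <- phantom_relax$fs
  }

  # corrected quantification (GTM-solved compartment means)
  if (isTRUE(cfg$corrections$pve)) {
    gtm <- gtm_correct(masks, op, corrected)
    solved <- gtm$solved[muscles]
  } else {
    gtm <- NULL
    solved <- vapply(masks[muscles], function(m) mean(corrected[m]),
                     numeric(1))
  }
  cal <- fit_calibration_curve(tube_means_corr)
  tsc_corr <- compute_tsc(solved, cal, tissue_relax, phantom_relax, prot)

  # uncorrected quantification: raw ROI means and raw tube calibration
  raw_means <- vapply(masks[muscles], function(m) mean(combined[m]),
                      numeric(1))
  cal_raw <- fit_calibration_curve(tube_means_raw)
  tsc_raw <- compute_tsc(raw_means, cal_raw, tissue_relax, phantom_relax,
                         prot)

  truth <- ph$label_table$tsc[match(muscles, ph$label_table$name)]
  add_truth <- function(res) {
    df <- res$table
    df$truth <- truth
    df$rel_error <- (df$tsc - df$truth) / df$truth
    df
  }
  tsc_tab <- add_truth(tsc_corr)
  tsc_tab_raw <- add_truth(tsc_raw)
  correction_gap <- 100 * (tsc_tab_raw$tsc - tsc_tab$tsc) / tsc_tab_raw$tsc

  relaxometry <- NULL
  if (isTRUE(cfg$run_relaxometry)) {
    # single receive channel suffices for ROI-mean relaxometry curves
    ph1 <- ph
    ph1$coil_sens <- ph$coil_sens[1]
    prot_t2 <- protocol_preset("t2star", matrix = cfg$matrix,
                               fov = cfg$fov, n_projections = n_proj)
    # relaxometry protocols use larger nominal voxels and long averaging,
    # hence substantially higher SNR than the 2.5 mm sodium protocol
    acq_t2 <- simulate_series(ph1, prot_t2, seed = cfg$seed + 6,
                              target_snr = 80, psf = psf, traj = traj)
    vols_t2 <- lapply(seq_along(acq_t2$contrast_values), function(ci) {
      rss_magnitude(acq_t2$volumes[[ci]])
    })
    roi_t2 <- extract_roi_series(vols_t2, masks[muscles],
                                 acq_t2$contrast_values)
    prot_t1 <- protocol_preset("t1_ir", matrix = cfg$matrix,
                               fov = cfg$fov, n_projections = n_proj)
    acq_t1 <- simulate_series(ph1, prot_t1, seed = cfg$seed + 7,
                              target_snr = 60, psf = psf, traj = traj)
    vols_t1 <- lapply(seq_along(acq_t1$contrast_values), function(ci) {
      rss_magnitude(acq_t1$volumes[[ci]])
    })
    roi_t1 <- extract_roi_series(vols_t1, masks[muscles],
                                 acq_t1$contrast_values)
    relaxometry <- list(
      t2star = relaxometry_table(roi_t2, "t2star"),
      t1 = relaxometry_table(roi_t1, "t1"))
  }

  structure(list(
    config = cfg,
    protocol = prot,
    phantom = ph,
    psf_fwhm = psf$fwhm,
    noise_sigma = acq$noise_sigma,
    snr_muscle = snr_muscle,
    fieldmaps = fieldmaps,
    calibration = cal,
    gtm = gtm,
    tsc = tsc_tab,
    tsc_uncorrected = tsc_tab_raw,
    correction_gap_percent = stats::setNames(correction_gap, muscles),
    relaxometry = relaxometry,
    runtime_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    package_version = as.character(utils::packageVersion("natriq"))
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline result: scenario '%s', matrix %d, SNR %.1f\n",
              x$config$scenario, x$config$matrix, x$snr_muscle))
  print(x$tsc[, c("muscle", "tsc", "truth", "rel_error")])
  cat("correction gap (%):",
      paste(sprintf("%s %.1f", names(x$correction_gap_percent),
                    x$correction_gap_percent), collapse = ", "), "\n")
  invisible(x)
}

#' Repeatability and group-comparison analysis of a TSC table
#'
#' Runs the full statistical battery on a long-format TSC table: per-muscle
#' two-way ICC (consistency/average-measures, with the absolute-agreement
#' variant alongside), Bland-Altman agreement for every session pair,
#' Friedman test across muscles on per-subject session means, pairwise
#' exact Wilcoxon signed-rank tests with Bonferroni correction, and exact
#' Wilcoxon rank-sum healthy-vs-patient comparisons per muscle.
#'
#' @param table long-format data.frame (see
#'   \code{\link{reference_tsc_table}}).
#' @return named list: \code{icc}, \code{icc_absolute}, \code{bland_altman},
#'   \code{friedman}, \code{pairwise}, \code{group_comparison},
#'   \code{means}.
#' @export
analyze_repeatability <- function(table = reference_tsc_table()) {
  muscles <- c("GM", "TA", "S")
  icc <- lapply(muscles, function(m) {
    icc_twoway(tsc_session_matrix(table, m), variant = "Ck")
  })
  icc_abs <- lapply(muscles, function(m) {
    icc_twoway(tsc_session_matrix(table, m), variant = "Ak")
  })
  names(icc) <- names(icc_abs) <- muscles
  sessions <- sort(unique(table$session[table$group == "healthy"]))
  pairs <- utils::combn(sessions, 2, simplify = FALSE)
  ba <- list()
  for (m in muscles) {
    for (p in pairs) {
      ba[[paste(m, paste(p, collapse = "-"), sep = ":")]] <-
        bland_altman(table[table$group == "healthy", ], m, p)
    }
  }
  subj_means <- tsc_subject_means(table, "healthy")
  fr <- friedman_test(subj_means)
  pairwise <- list(
    "GM-TA" = wilcoxon_signed_rank(subj_means[, "GM"], subj_means[, "TA"],
                                   m_comparisons = 3),
    "GM-S" = wilcoxon_signed_rank(subj_means[, "GM"], subj_means[, "S"],
                                  m_comparisons = 3),
    "TA-S" = wilcoxon_signed_rank(subj_means[, "TA"], subj_means[, "S"],
                                  m_comparisons = 3))
  add_means <- tsc_subject_means(table, "addison")
  group_cmp <- lapply(muscles, function(m) {
    wilcoxon_rank_sum(subj_means[, m], add_means[, m])
  })
  names(group_cmp) <- muscles
  means <- list(
    healthy = colMeans(subj_means),
    healthy_sd = apply(subj_means, 2, sd),
    addison = colMeans(add_means),
    addison_sd = apply(add_means, 2, sd))
  list(icc = icc, icc_absolute = icc_abs, bland_altman = ba,
       friedman = fr, pairwise = pairwise, group_comparison = group_cmp,
       means = means)
}

#' Write the synthetic fixture bundle
#'
#' Deterministically writes the digital phantoms (healthy, Addison,
#' cylinder) as NIfTI label/field volumes with JSON sidecars, a sodium
#' acquisition series of the healthy phantom, the muscle masks, the
#' packaged reference measurement tables, and the protocol presets.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param matrix matrix size of the written phantoms (default 48 keeps the
#'   bundle small).
#' @return invisibly, the vector of written paths.
#' @export
generate_fixtures <- function(out_dir, seed = 20220719, matrix = 48) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory")
  probe <- file.path(out_dir, ".write_test")
  if (!isTRUE(tryCatch({ file.create(probe) }, error = function(e) FALSE))) {
    stop("output directory not writable")
  }
  unlink(probe)
  paths <- character(0)
  for (sc in c("healthy", "addison", "cylinder")) {
    ph <- make_digital_phantom(matrix, sc, seed = seed)
    paths <- c(paths, write_phantom_nifti(
      ph, file.path(out_dir, paste0("phantom_", sc))))
  }
  ph <- make_digital_phantom(matrix, "healthy", seed = seed)
  prot <- protocol_preset("sodium", matrix = matrix)
  acq <- simulate_series(ph, prot, seed = seed)
  paths <- c(paths, write_series_nifti(acq, file.path(out_dir,
                                                      "sodium_healthy")))
  tab4 <- reference_tsc_table()
  tab3 <- reference_relaxation_table()
  p1 <- file.path(out_dir, "cohort_tsc_sessions.csv")
  p2 <- file.path(out_dir, "cohort_relaxation_times.csv")
  utils::write.csv(tab4, p1, row.names = FALSE)
  utils::write.csv(tab3, p2, row.names = FALSE)
  p3 <- file.path(out_dir, "protocols.yaml")
  file.copy(system.file("extdata", "protocols.yaml", package = "natriq"),
            p3, overwrite = TRUE)
  invisible(c(paths, p1, p2, p3))
}
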