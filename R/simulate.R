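# Forward simulation of multi-echo / inversion-recovery 23Na acquisitions
# on a digital phantom.

# Circular convolution of a (complex) volume with a precomputed kernel FFT
# (kernel peak aligned to index 1,1,1 before transforming).
.conv_circular <- function(arr, kern_hat) {
  fft(fft(arr) * kern_hat, inverse = TRUE) / length(arr)
}

.psf_fft <- function(psf_grid) {
  pk <- which(psf_grid == max(psf_grid), arr.ind = TRUE)[1, ]
  fft(circshift(psf_grid, -(pk - 1)))
}

# Kernel FFT on a zero-padded (2x) grid; with .conv_padded this matches the
# non-wrapping behaviour of the oversampled gridding reconstruction.
.psf_fft_padded <- function(psf_grid) {
  dk <- dim(psf_grid)
  pk <- which(psf_grid == max(psf_grid), arr.ind = TRUE)[1, ]
  kp <- array(0, 2 * dk)
  kp[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- psf_grid
  fft(circshift(kp, -(pk - 1)))
}

.conv_padded <- function(arr, kern_hat_padded) {
  d <- dim(arr)
  ap <- array(0i, 2 * d)
  ap[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  out <- fft(fft(ap) * kern_hat_padded, inverse = TRUE) / length(ap)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
}

# Cohort-mean transverse decay used for PSF simulation (healthy-subject
# values, short/long fractions 60/40).
.COHORT_DECAY <- list(t2s = 3.3, t2l = 12.9, fs = 60)

#' Simulate a multi-contrast acquisition series on a digital phantom
#'
#' For each contrast (echo time, or inversion time for IR protocols) the
#' ideal image is the per-voxel closed-form signal
#' (\code{\link{steady_state_signal}}; for IR series the signed factor
#' \code{1 - 2 exp(-TI/T1)} replaces saturation), scaled by the transmit
#' profile \code{sin(flip * b1)} and each coil's complex sensitivity. In
#' \code{"image_psf"} mode the shaded image is blurred by the protocol's
#' simulated PSF (circular convolution on the periodic reconstruction grid);
#' in \code{"kspace"} mode it is forward-sampled on the DA-3DPR trajectory
#' (with bi-exponential decay along the readout and optional per-voxel B0
#' phase) and reconstructed by gridding. Complex Gaussian noise of standard
#' deviation \code{noise_sigma} is added per channel, and matching
#' noise-only volumes are appended.
#'
#' @param ph a \code{digital_phantom}.
#' @param prot an \code{acquisition_protocol} on the same matrix.
#' @param mode \code{"image_psf"} (fast, default) or \code{"kspace"}.
#' @param seed integer seed for the noise.
#' @param noise_sigma per-channel complex-noise sd; \code{NULL} calibrates it
#'   so that the mean object signal-to-noise ratio of the first contrast is
#'   \code{target_snr}.
#' @param target_snr SNR calibration target (default 16, the healthy-calf
#'   sodium-image value this simulator emulates).
#' @param psf optional precomputed \code{psf} object (image_psf mode).
#' @param traj optional precomputed trajectory (kspace mode).
#' @param include_b0 include the phantom's B0 map as per-voxel off-resonance
#'   phase (kspace mode only; default FALSE).
#' @param n_noise number of noise-only volumes (default 2).
#' @param psf_decay apply cohort-mean bi-exponential T2* decay along the
#'   readout when simulating the PSF (default TRUE).
#' @return an \code{acquisition_series}: \code{volumes} (list over contrasts
#'   of lists over coils of complex 3D arrays), \code{contrast_values},
#'   \code{contrast_type} ("te" or "ti"), \code{noise_only}, \code{protocol},
#'   \code{noise_sigma}, \code{seed}, \code{psf}.
#' @export
simulate_series <- function(ph, prot, mode = c("image_psf", "kspace"),
                            seed = 20220719, noise_sigma = NULL,
                            target_snr = 16, psf = NULL, traj = NULL,
                            include_b0 = FALSE, n_noise = 2,
                            psf_decay = TRUE) {
  stopifnot(inherits(ph, "digital_phantom"),
            inherits(prot, "acquisition_protocol"))
  mode <- match.arg(mode)
  if (ph$matrix != prot$matrix) stop("phantom and protocol grids differ")
  n <- ph$matrix
  is_ir <- length(prot$ti_list) > 0
  contrast_values <- if (is_ir) prot$ti_list else prot$te_list
  if (any(contrast_values < 0) || any(contrast_values > 1e4)) {
    stop("contrast times outside physical range")
  }
  tab <- ph$label_table
  flip_nom <- prot$flip_nominal

  # per-label signal level at each contrast (spatial shading excluded)
  levels <- vapply(seq_along(contrast_values), function(ci) {
    if (is_ir) {
      tr_i <- if (length(prot$tr) >= ci) prot$tr[ci] else prot$tr[1]
      ir_signal(tab$tsc, tab$t1, tab$t2s, tab$t2l, tab$fs,
                ti = contrast_values[ci], te = prot$te_list[1])
    } else {
      steady_state_signal(tab$tsc, tab$t1, tab$t2s, tab$t2l, tab$fs,
                          tr = prot$tr[1], te = contrast_values[ci])
    }
  }, numeric(nrow(tab)))

  transmit <- sin(flip_nom * ph$b1_map * pi / 180)
  present <- which(tab$tsc > 0 & tab$label %in% unique(as.vector(ph$labels)))
  n_coils <- length(ph$coil_sens)

  dec <- if (psf_decay) .COHORT_DECAY else list(t2s = NULL, t2l = NULL,
                                                fs = NULL)
  if (mode == "image_psf") {
    if (is.null(traj)) traj <- protocol_trajectory(prot)
    if (is.null(psf)) {
      psf <- simulate_psf(traj, n, method = "gridding",
                          t2s = dec$t2s, t2l = dec$t2l, fs = dec$fs)
    }
    op <- psf_operator(traj, n, t2s = dec$t2s, t2l = dec$t2l, fs = dec$fs)
    # imaging-operator response of each shaded compartment indicator per
    # (label, coil); contrasts are then linear combinations of these basis
    # volumes, so the expensive operator runs once per compartment, not
    # once per echo
    basis <- lapply(present, function(li) {
      ind <- (ph$labels == tab$label[li]) * transmit
      lapply(seq_len(n_coils), function(k) {
        op(ind * ph$coil_sens[[k]])
      })
    })
    make_volume <- function(ci, k) {
      acc <- array(0i, dim = rep(n, 3))
      for (j in seq_along(present)) {
        acc <- acc + levels[present[j], ci] * basis[[j]][[k]]
      }
      acc
    }
  } else {
    if (is.null(traj)) traj <- protocol_trajectory(prot)
    psf <- NULL
    tms <- trajectory_times(traj)
    decay <- if (psf_decay) {
      (dec$fs / 100) * exp(-tms / dec$t2s) +
        (1 - dec$fs / 100) * exp(-tms / dec$t2l)
    } else rep(1, length(tms))
    tsc_map0 <- phantom_param_map(ph, "tsc")
    make_volume <- function(ci, k) {
      lvl_map <- array(levels[, ci][match(ph$labels, tab$label)],
                       dim = dim(ph$labels))
      ideal <- lvl_map * transmit * ph$coil_sens[[k]]
      if (include_b0) {
        rng <- range(ph$b0_map[tsc_map0 > 0])
        n_bins <- 8
        edges <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1)
        mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
        bin <- findInterval(ph$b0_map, edges, all.inside = TRUE)
        kdata <- complex(real = numeric(length(tms)))
        for (bi in seq_len(n_bins)) {
          sub <- ideal * (bin == bi)
          if (all(sub == 0)) next
          kdata <- kdata + forward_sample(sub, traj) *
            exp(2i * pi * mids[bi] * tms * 1e-3)
        }
      } else {
        kdata <- forward_sample(ideal, traj)
      }
      grid_reconstruct(kdata * decay, traj, n)
    }
  }

  volumes <- lapply(seq_along(contrast_values), function(ci) {
    lapply(seq_len(n_coils), function(k) make_volume(ci, k))
  })

  if (is.null(noise_sigma)) {
    if (is.null(target_snr) || !is.finite(target_snr)) {
      noise_sigma <- 0
    } else {
      comb <- sqrt(Reduce(`+`, lapply(volumes[[1]], function(v) Mod(v)^2)))
      obj <- ph$labels %in% tab$label[tab$label %in% 1:4 & tab$tsc > 0]
      if (!any(obj)) obj <- ph$labels > 0
      noise_sigma <- mean(comb[obj]) / target_snr
    }
  }

  noise_only <- list()
  if (noise_sigma > 0) {
    with_seed(seed, {
      volumes <- lapply(volumes, function(coils) {
        lapply(coils, function(v) v + complex_noise(dim(v), noise_sigma))
      })
      noise_only <- lapply(seq_len(n_noise), function(i) {
        lapply(seq_len(n_coils), function(k) {
          complex_noise(rep(n, 3), noise_sigma)
        })
      })
    })
  } else {
    noise_only <- lapply(seq_len(n_noise), function(i) {
      lapply(seq_len(n_coils), function(k) array(0i, dim = rep(n, 3)))
    })
  }

  structure(list(
    volumes = volumes,
    contrast_values = contrast_values,
    contrast_type = if (is_ir) "ti" else "te",
    noise_only = noise_only,
    protocol = prot,
    noise_sigma = noise_sigma,
    seed = as.integer(seed),
    mode = mode,
    psf = psf
  ), class = "acquisition_series")
}

#' @export
print.acquisition_series <- function(x, ...) {
  cat(sprintf(
    "acquisition series: %d %s contrasts, %d coil(s), sigma %.4g (%s mode)\n",
    length(x$contrast_values), toupper(x$contrast_type),
    length(x$volumes[[1]]), x$noise_sigma, x$mode))
  invisible(x)
}

#' Coil-combined magnitude volume of one contrast
#'
#' Adaptive combination (\code{\link{adaptive_combine}}) when several coils
#' are present, plain magnitude otherwise.
#'
#' @param acq an \code{acquisition_series}.
#' @param contrast contrast index (default 1).
#' @return real 3D array (magnitude image).
#' @export
combined_magnitude <- function(acq, contrast = 1) {
  coils <- acq$volumes[[contrast]]
  if (length(coils) == 1) return(Mod(coils[[1]]))
  Mod(adaptive_combine(simplify2array(coils)))
}

#' Export an acquisition series as NIfTI files plus JSON sidecar
#'
#' One magnitude NIfTI per contrast (coil-combined) and a sidecar with
#' protocol, contrast values, noise level and seed.
#'
#' @param acq an \code{acquisition_series}.
#' @param prefix output path prefix.
#' @return invisibly, the written paths.
#' @export
write_series_nifti <- function(acq, prefix) {
  stopifnot(inherits(acq, "acquisition_series"))
  vox <- acq$protocol$resolution
  paths <- character(0)
  for (ci in seq_along(acq$contrast_values)) {
    p <- sprintf("%s_%s%02d.nii", prefix, acq$contrast_type, ci)
    img <- RNifti::asNifti(combined_magnitude(acq, ci))
    RNifti::pixdim(img) <- rep(vox, 3)
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  sidecar <- paste0(prefix, ".json")
  jsonlite::write_json(list(
    protocol = unclass(acq$protocol),
    contrast_type = acq$contrast_type,
    contrast_values = acq$contrast_values,
    noise_sigma = acq$noise_sigma,
    seed = acq$seed, mode = acq$mode
  ), sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, sidecar))
}
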