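# Coil combination, SNR mapping, B0/B1+ estimation, and intensity /
# off-resonance corrections.

# Successive linear interpolation of node values (array over a coarse node
# lattice at 1-based voxel positions node_pos[[d]]) onto a full grid.
.lattice_interp <- function(nodes, node_pos, target_dim) {
  arr <- nodes
  for (ax in 1:3) {
    arr <- aperm(arr, c(ax, setdiff(1:3, ax)))
    da <- dim(arr)
    xout <- seq_len(target_dim[ax])
    if (da[1] == 1) {
      arr <- array(rep(as.vector(arr), each = target_dim[ax]),
                   dim = c(target_dim[ax], da[2], da[3]))
    } else {
      arr <- array(apply(arr, 2:3, function(v) {
        approx(node_pos[[ax]], v, xout = xout, rule = 2)$y
      }), dim = c(target_dim[ax], da[2], da[3]))
    }
    arr <- aperm(arr, order(c(ax, setdiff(1:3, ax))))
    node_pos[[ax]] <- xout
  }
  arr
}

#' Adaptive (Walsh-type) coil combination in 3D
#'
#' Estimates relative coil sensitivities as the dominant eigenvector of the
#' local coil covariance matrix in overlapping blocks on a coarse lattice,
#' interpolates them smoothly to every voxel, and combines the coil images
#' as the sensitivity-weighted (matched-filter) sum.
#'
#' @param coil_volumes complex 4D array (x, y, z, coil).
#' @param block_size block edge length in voxels (default 8).
#' @param block_overlap overlap between neighbouring blocks in voxels
#'   (default 8); together with \code{interp_factor} it sets the lattice
#'   stride \code{max(1, block_size - block_overlap/2)}.
#' @param interp_factor sensitivity-interpolation factor (default 2; kept
#'   for protocol fidelity, the lattice is always interpolated smoothly).
#' @return combined complex 3D volume.
#' @export
adaptive_combine <- function(coil_volumes, block_size = 8,
                             block_overlap = 8, interp_factor = 2) {
  d <- dim(coil_volumes)
  if (length(d) == 3) return(coil_volumes)
  stopifnot(length(d) == 4)
  nc <- d[4]
  if (nc == 1) return(coil_volumes[, , , 1])
  dims <- d[1:3]
  if (block_size > min(dims)) stop("block larger than volume")
  stride <- max(1, block_size - block_overlap %/% 2)
  node_pos <- lapply(dims, function(n) {
    p <- unique(c(seq(1 + block_size %/% 2, n - block_size %/% 2 + 1,
                      by = stride), n - block_size %/% 2 + 1))
    if (length(p) < 2) p <- c(1, n)
    p
  })
  # phase-reference coil: highest total power
  power <- vapply(seq_len(nc), function(k) {
    sum(Mod(coil_volumes[, , , k])^2)
  }, numeric(1))
  ref <- which.max(power)
  nn <- vapply(node_pos, length, integer(1))
  sens_nodes <- array(0i, dim = c(nn, nc))
  node_power <- array(0, dim = nn)
  hb <- block_size %/% 2
  for (iz in seq_len(nn[3])) {
    zr <- max(1, node_pos[[3]][iz] - hb):min(dims[3], node_pos[[3]][iz] + hb)
    for (iy in seq_len(nn[2])) {
      yr <- max(1, node_pos[[2]][iy] - hb):min(dims[2], node_pos[[2]][iy] + hb)
      for (ix in seq_len(nn[1])) {
        xr <- max(1, node_pos[[1]][ix] - hb):
          min(dims[1], node_pos[[1]][ix] + hb)
        S <- vapply(seq_len(nc), function(k) {
          as.vector(coil_volumes[xr, yr, zr, k])
        }, complex(length(xr) * length(yr) * length(zr)))
        R <- crossprod(S, Conj(S))   # R[p, q] = sum_v x_p conj(x_q)
        v <- eigen(R, symmetric = TRUE)$vectors[, 1]
        v <- v * exp(-1i * Arg(v[ref]))
        sens_nodes[ix, iy, iz, ] <- v
        node_power[ix, iy, iz] <- sum(Mod(R))
      }
    }
  }
  # blocks with (near-)zero signal have arbitrary eigenvectors; replace them
  # with the nearest signal-bearing block's estimate before interpolating
  valid <- node_power > 1e-8 * max(node_power)
  if (any(valid) && !all(valid)) {
    vi <- which(valid, arr.ind = TRUE)
    ii <- which(!valid, arr.ind = TRUE)
    for (r in seq_len(nrow(ii))) {
      d2 <- (vi[, 1] - ii[r, 1])^2 + (vi[, 2] - ii[r, 2])^2 +
        (vi[, 3] - ii[r, 3])^2
      src <- vi[which.min(d2), ]
      sens_nodes[ii[r, 1], ii[r, 2], ii[r, 3], ] <-
        sens_nodes[src[1], src[2], src[3], ]
    }
  }
  # eigenvectors carry an arbitrary per-node phase; align each node to an
  # already-aligned raster neighbour so interpolation does not cancel
  for (iz in seq_len(nn[3])) {
    for (iy in seq_len(nn[2])) {
      for (ix in seq_len(nn[1])) {
        if (ix == 1 && iy == 1 && iz == 1) next
        nb <- if (ix > 1) sens_nodes[ix - 1, iy, iz, ]
        else if (iy > 1) sens_nodes[ix, iy - 1, iz, ]
        else sens_nodes[ix, iy, iz - 1, ]
        v <- sens_nodes[ix, iy, iz, ]
        ip <- sum(Conj(nb) * v)
        if (Mod(ip) > 0) {
          sens_nodes[ix, iy, iz, ] <- v * exp(-1i * Arg(ip))
        }
      }
    }
  }
  sens <- lapply(seq_len(nc), function(k) {
    re <- .lattice_interp(array(Re(sens_nodes[, , , k]), dim = nn),
                          node_pos, dims)
    im <- .lattice_interp(array(Im(sens_nodes[, , , k]), dim = nn),
                          node_pos, dims)
    re + 1i * im
  })
  norm2 <- Reduce(`+`, lapply(sens, function(s) Mod(s)^2))
  norm2[norm2 == 0] <- 1
  out <- array(0i, dim = dims)
  for (k in seq_len(nc)) {
    out <- out + Conj(sens[[k]]) * coil_volumes[, , , k]
  }
  out <- out / sqrt(norm2)
  attr(out, "sens") <- sens
  out
}

#' Multiple-replica SNR map
#'
#' Pseudo-replica method: synthetic noise matching the measured noise-only
#' statistics is repeatedly added to the data, each replica is passed through
#' the reconstruction, and the per-voxel SNR is the replica mean divided by
#' the replica standard deviation.
#'
#' @param x an \code{acquisition_series} (its noise-only volumes provide the
#'   noise level) or a complex/real 3D volume.
#' @param noise_sigma per-channel noise sd, required when \code{x} is a bare
#'   volume without \code{noise_only}.
#' @param noise_only optional list of noise-only volumes used to estimate
#'   \code{noise_sigma}.
#' @param n_replicas number of replicas (>= 2, default 100).
#' @param seed RNG seed.
#' @param recon_fun reconstruction applied to each replica: for a series, a
#'   function of the list of per-coil complex volumes (default: adaptive
#'   combination magnitude); for a bare volume, a function of the volume
#'   (default \code{Mod}).
#' @param contrast contrast index used for a series (default 1).
#' @return object of class \code{snr_map}: \code{snr} (3D array),
#'   \code{n_replicas}, \code{noise_sigma}.
#' @export
multiple_replica_snr <- function(x, noise_sigma = NULL, noise_only = NULL,
                                 n_replicas = 100, seed = 1,
                                 recon_fun = NULL, contrast = 1) {
  if (n_replicas < 2) stop("n_replicas must be >= 2")
  if (inherits(x, "acquisition_series")) {
    if (is.null(noise_only)) noise_only <- x$noise_only
    if (is.null(noise_only) || length(noise_only) == 0) {
      stop("noise-only volumes are required to estimate the noise level")
    }
    if (is.null(noise_sigma)) {
      vals <- unlist(lapply(noise_only, function(coils) {
        lapply(coils, function(v) c(Re(v), Im(v)))
      }))
      noise_sigma <- sd(vals)
    }
    coils <- x$volumes[[contrast]]
    if (is.null(recon_fun)) {
      recon_fun <- function(cl) {
        if (length(cl) == 1) Mod(cl[[1]]) else Mod(adaptive_combine(
          simplify2array(cl)))
      }
    }
    make_replica <- function() {
      recon_fun(lapply(coils, function(v) {
        v + complex_noise(dim(v), noise_sigma)
      }))
    }
    dims <- dim(coils[[1]])
  } else {
    if (is.null(noise_sigma)) {
      if (is.null(noise_only)) {
        stop("noise_sigma or noise_only volumes required")
      }
      vals <- unlist(lapply(noise_only, function(v) c(Re(v), Im(v))))
      noise_sigma <- sd(vals)
    }
    if (is.null(recon_fun)) recon_fun <- Mod
    make_replica <- function() {
      recon_fun(x + complex_noise(dim(x), noise_sigma))
    }
    dims <- dim(x)
  }
  with_seed(seed, {
    s1 <- array(0, dims)
    s2 <- array(0, dims)
    for (r in seq_len(n_replicas)) {
      rep_r <- make_replica()
      s1 <- s1 + rep_r
      s2 <- s2 + rep_r^2
    }
  })
  m <- s1 / n_replicas
  v <- pmax(0, s2 / n_replicas - m^2) * n_replicas / (n_replicas - 1)
  snr <- m / sqrt(v)
  snr[!is.finite(snr)] <- 0
  structure(list(snr = snr, n_replicas = as.integer(n_replicas),
                 noise_sigma = noise_sigma), class = "snr_map")
}

#' Dual-echo B0 field map
#'
#' Off-resonance in Hz from the phase evolution between two echoes:
#' \code{b0 = Arg(echo2 * Conj(echo1)) / (2 pi (te2 - te1))}. The map is
#' single-wrap: offsets beyond \code{+/- 1/(2 dTE)} alias back into that
#' band.
#'
#' @param echo1,echo2 complex 3D volumes at \code{te1 < te2} (ms).
#' @param te1,te2 echo times in ms.
#' @param mask_rel relative magnitude threshold defining the support mask.
#' @return object of class \code{field_maps} with \code{b0} (Hz, NA outside
#'   support), \code{support_mask}.
#' @export
b0_map_dual_echo <- function(echo1, echo2, te1, te2, mask_rel = 0.1) {
  if (te2 <= te1) stop("te2 must exceed te1")
  dte_s <- (te2 - te1) * 1e-3
  b0 <- Arg(echo2 * Conj(echo1)) / (2 * pi * dte_s)
  support <- Mod(echo1) > mask_rel * max(Mod(echo1))
  b0[!support] <- NA_real_
  structure(list(b0 = b0, b1 = NULL, support_mask = support),
            class = "field_maps")
}

# --- phase-sensitive B1+ mapping ------------------------------------------

#' Transverse magnetization after the composite B1-mapping pulse
#'
#' Rotation by \code{2*alpha} about x followed by \code{alpha} about y,
#' applied to equilibrium magnetization; returns \code{Mx + i My}. The
#' phase of this quantity versus actual flip is the relation the
#' phase-sensitive B1 map inverts.
#'
#' @param alpha_deg actual flip angle(s) of the y pulse, degrees.
#' @return complex vector.
#' @export
composite_pulse_mxy <- function(alpha_deg) {
  a <- alpha_deg * pi / 180
  complex(real = cos(2 * a) * sin(a), imaginary = -sin(2 * a))
}

# Unwrapped phase-vs-flip lookup over the invertible domain (10, 170) deg.
.b1_lookup <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    alpha <- seq(10, 170, by = 0.05)
    ph <- Arg(composite_pulse_mxy(alpha))
    dp <- diff(ph)
    dp <- dp - 2 * pi * round(dp / (2 * pi))
    unwrapped <- ph[1] + c(0, cumsum(dp))
    if (any(diff(unwrapped) >= 0)) {
      stop("composite-pulse phase not strictly monotone")  # nocov
    }
    cache <<- list(alpha = alpha, phase = unwrapped)
    cache
  }
})

#' Phase-sensitive B1+ map
#'
#' Recovers the actual flip angle per voxel from the phase of a composite
#' (2a about x, then a about y) preparation relative to a plain-excitation
#' reference. The phase-vs-flip relation of the composite rotation is
#' tabulated from the rotation model and inverted over actual flips in
#' (10, 170) degrees; voxels whose phase falls outside the invertible domain
#' are flagged invalid (NA).
#'
#' @param prepared complex 3D volume acquired with the composite pulse pair
#'   (nominal 180 about x, 90 about y at unit B1).
#' @param reference complex 3D volume with plain excitation on the same grid.
#' @param flip_nominal nominal flip angle of the y pulse in degrees
#'   (default 90).
#' @param mask_rel relative magnitude threshold for the support mask.
#' @return \code{field_maps} with \code{b1} = actual/nominal flip (NA where
#'   invalid), \code{support_mask}.
#' @export
b1_map_phase_sensitive <- function(prepared, reference, flip_nominal = 90,
                                   mask_rel = 0.1) {
  if (!all(dim(prepared) == dim(reference))) {
    stop("prepared and reference volumes must share a grid")
  }
  lk <- .b1_lookup()
  delta <- Arg(prepared * Conj(reference))
  lo <- min(lk$phase)
  hi <- max(lk$phase)
  target <- delta
  shift_down <- !is.na(target) & target > hi
  target[shift_down] <- target[shift_down] - 2 * pi
  invalid <- !is.finite(target) | target < lo | target > hi
  alpha <- approx(lk$phase, lk$alpha, xout = pmin(pmax(target, lo), hi))$y
  b1 <- alpha / flip_nominal
  support <- Mod(reference) > mask_rel * max(Mod(reference))
  b1[invalid | !support] <- NA_real_
  b1 <- array(b1, dim = dim(prepared))
  structure(list(b0 = NULL, b1 = b1, support_mask = support & !invalid),
            class = "field_maps")
}

#' Simulate a phase-sensitive B1-mapping acquisition pair
#'
#' Forward model used by the pipeline: the prepared volume carries the
#' composite-pulse transverse magnetization at the local actual flip
#' \code{flip_nominal * b1}, the reference a plain excitation, both scaled
#' by the object's relaxation-weighted concentration.
#'
#' @param ph a \code{digital_phantom}.
#' @param prot acquisition protocol providing TR/TE weighting.
#' @return list with complex volumes \code{prepared} and \code{reference}.
#' @export
simulate_b1_pair <- function(ph, prot) {
  tab <- ph$label_table
  lvl <- steady_state_signal(tab$tsc, tab$t1, tab$t2s, tab$t2l, tab$fs,
                             tr = prot$tr[1], te = prot$te_list[1])
  mag <- array(lvl[match(ph$labels, tab$label)], dim = dim(ph$labels))
  alpha <- prot$flip_nominal * ph$b1_map
  prepared <- mag * composite_pulse_mxy(alpha)
  reference <- mag * sin(alpha * pi / 180)
  list(prepared = prepared, reference = reference)
}

#' Conjugate-phase (multi-frequency) off-resonance correction
#'
#' Reconstructs the data set at several demodulation frequencies spanning
#' the B0 range and assembles the corrected image by selecting, per voxel,
#' the reconstruction demodulated closest to that voxel's off-resonance.
#'
#' @param kspace_data complex per-sample k-space data.
#' @param traj the \code{radial_trajectory} the data were sampled on.
#' @param b0 off-resonance map in Hz (array on the image grid, NA allowed)
#'   or a \code{field_maps} object.
#' @param grid_size output matrix size.
#' @param n_freq_bins number of demodulation frequencies (default 20).
#' @return corrected complex 3D volume.
#' @export
correct_off_resonance <- function(kspace_data, traj, b0, grid_size,
                                  n_freq_bins = 20) {
  if (inherits(b0, "field_maps")) b0 <- b0$b0
  tms <- trajectory_times(traj) * 1e-3
  vals <- b0[is.finite(b0)]
  if (length(vals) == 0) vals <- 0
  rng <- range(vals)
  if (diff(rng) < 1e-9 || n_freq_bins == 1) {
    freqs <- mean(rng)
  } else {
    freqs <- seq(rng[1], rng[2], length.out = n_freq_bins)
  }
  recons <- lapply(freqs, function(f) {
    grid_reconstruct(kspace_data * exp(-2i * pi * f * tms), traj, grid_size)
  })
  if (length(freqs) == 1) return(recons[[1]])
  b0f <- b0
  b0f[!is.finite(b0f)] <- 0
  sel <- vapply(as.vector(b0f), function(v) which.min(abs(freqs - v)),
                integer(1))
  out <- array(0i, dim = rep(grid_size, 3))
  for (bi in seq_along(freqs)) {
    pick <- array(sel == bi, dim = dim(out))
    out[pick] <- recons[[bi]][pick]
  }
  out
}

#' Derive intensity-correction factors from the homogeneous cylinder and
#' apply them
#'
#' The homogeneous 61.6 mmol/L cylinder fills the coil, so any structure in
#' its image is instrumental shading (transmit and receive field
#' inhomogeneity). The per-voxel gain is nominal level / smoothed observed
#' cylinder intensity; because the shading fields are axially smooth, the
#' gain is derived from a central slab (away from the cylinder's own
#' partial-volume end effects) and replicated along z. Voxels with
#' near-zero observed intensity are flagged and assigned gain 1.
#'
#' @param invivo real 3D volume to correct (magnitude image).
#' @param cylinder_image real 3D magnitude image of the homogeneous cylinder
#'   acquired with the same geometry and shading.
#' @param nominal nominal cylinder level (default: mean over the support).
#' @param smooth_sd Gaussian smoothing sd of the gain field in voxels
#'   (default 2).
#' @param mask_rel relative threshold defining the cylinder support.
#' @param slab_fraction central z-fraction of slices used to derive the 2D
#'   gain (default 0.5); set to \code{NULL} to use the full 3D volume.
#' @return list with \code{corrected} (real 3D array) and \code{factors}
#'   (class \code{correction_factors}: \code{intensity_gain},
#'   \code{support}, \code{n_flagged}, \code{provenance}).
#' @export
derive_and_apply_correction <- function(invivo, cylinder_image,
                                        nominal = NULL, smooth_sd = 2,
                                        mask_rel = 0.2,
                                        slab_fraction = 0.5) {
  d <- dim(cylinder_image)
  if (!all(dim(invivo) == d)) stop("grids not aligned")
  if (!is.null(slab_fraction)) {
    nz <- d[3]
    keep <- abs(seq_len(nz) - (nz + 1) / 2) <= slab_fraction * nz / 2
    slab <- apply(cylinder_image[, , keep, drop = FALSE], c(1, 2), mean)
    cyl <- array(rep(slab, times = d[3]), dim = d)
  } else {
    cyl <- cylinder_image
  }
  support <- cyl > mask_rel * stats::quantile(cyl, 0.95)
  if (is.null(nominal)) nominal <- mean(cyl[support])
  # normalized convolution: smoothing does not bleed across the support edge
  num <- gauss_smooth3(cyl * support, smooth_sd)
  den <- gauss_smooth3(support + 0, smooth_sd)
  smoothed <- array(nominal, dim = d)
  smoothed[support] <- num[support] / pmax(den[support], 1e-6)
  near_zero <- smoothed < 0.05 * nominal
  gain <- nominal / pmax(smoothed, 0.05 * nominal)
  gain[!support | near_zero] <- 1
  factors <- structure(list(intensity_gain = gain, support = support,
                            n_flagged = sum(near_zero & support),
                            provenance = "homogeneous cylinder phantom"),
                       class = "correction_factors")
  list(corrected = invivo * gain, factors = factors)
}
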