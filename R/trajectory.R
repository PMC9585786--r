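# Density-adapted 3D radial projection (DA-3DPR) sampling geometry.

#' Build a density-adapted 3D radial (DA-3DPR) trajectory
#'
#' Constructs the center-out radial k-space sampling geometry of a
#' density-adapted 3D projection-reconstruction sequence. Spoke directions
#' follow a deterministic golden-means spiral over the full sphere; along
#' each spoke the radial position grows linearly with time up to the
#' transition radius \code{k0 = t0_fraction * kmax} and then follows the
#' cube-root law \code{k(t) = (k0^3 + 3 k0^2 c (t - t0))^(1/3)}, which makes
#' the sample density per unit k-space volume constant beyond \code{k0}
#' (equivalently, the gradient is ramped down so that \code{dk/dt} falls off
#' as \code{k^-2}).
#'
#' @param n_spokes number of radial projections (>= 1).
#' @param matrix nominal reconstruction matrix size (isotropic).
#' @param resolution nominal voxel size in mm; \code{kmax = 1/(2*resolution)}.
#' @param t0_fraction fraction of \code{kmax} reached by the constant-gradient
#'   portion; \code{1} disables density adaptation (pure radial readout).
#' @param n_samples_per_spoke samples per spoke (default \code{4 * matrix}:
#'   four-fold radial readout oversampling, enough to keep the short
#'   constant-gradient ramp portion, which covers k0 in a small fraction of
#'   the readout, radially Nyquist-sampled for objects filling the FOV).
#' @param readout_duration total readout duration per spoke in ms, used to
#'   attach physical times to the samples (off-resonance and decay modeling).
#' @return An object of class \code{radial_trajectory} with fields
#'   \code{directions} (unit vectors, one row per spoke), \code{k_radii} and
#'   \code{density_weights} (per sample along a spoke, shared by all spokes),
#'   \code{sample_times} (ms), \code{k0}, \code{kmax} (1/mm) and the
#'   \code{gamma} constant 11.262 MHz/T of the 23Na nucleus.
#' @export
build_da3dpr_trajectory <- function(n_spokes, matrix, resolution,
                                    t0_fraction = 0.25,
                                    n_samples_per_spoke = 4 * matrix,
                                    readout_duration = 10) {
  if (length(n_spokes) != 1 || n_spokes < 1) {
    stop("n_spokes must be a single value >= 1")
  }
  if (resolution <= 0) stop("resolution must be > 0 mm")
  if (t0_fraction <= 0 || t0_fraction > 1) {
    stop("t0_fraction must lie in (0, 1]")
  }
  if (n_samples_per_spoke < 2) stop("need at least 2 samples per spoke")
  n_spokes <- as.integer(n_spokes)
  ns <- as.integer(n_samples_per_spoke)
  kmax <- 1 / (2 * resolution)
  k0 <- t0_fraction * kmax

  # Golden-means spiral: quasi-uniform deterministic spoke directions.
  i <- seq_len(n_spokes) - 1
  z <- 1 - 2 * (i + 0.5) / n_spokes
  golden <- (1 + sqrt(5)) / 2
  phi <- 2 * pi * i / golden
  s <- sqrt(pmax(0, 1 - z^2))
  directions <- cbind(x = s * cos(phi), y = s * sin(phi), z = z)

  # Normalized readout time in [0, 1]; constant gradient until t0, then the
  # cube-root law with slope-continuity constant c = k0 / t0.
  f <- t0_fraction
  t0 <- if (f >= 1) 1 else 1 / (1 + ((1 / f)^3 - 1) / 3)
  cc <- k0 / t0
  k_of_t <- function(t) {
    ifelse(t <= t0, k0 * t / t0,
           (k0^3 + 3 * k0^2 * cc * (t - t0))^(1 / 3))
  }
  tt <- (seq_len(ns) - 0.5) / ns
  k_radii <- k_of_t(tt)
  # density weight = exact k-space volume element per sample: the spherical
  # shell between the half-sample radii (divided among spokes; the constant
  # factor is irrelevant). Equals k^2 dk in the continuum limit but keeps
  # the DC region correctly weighted at coarse radial sampling.
  k_edges <- k_of_t(seq(0, ns) / ns)
  density_weights <- diff(k_edges^3) / 3
  density_weights <- pmax(density_weights, .Machine$double.eps)

  structure(list(
    n_spokes = n_spokes,
    n_samples_per_spoke = ns,
    directions = directions,
    k_radii = k_radii,
    density_weights = density_weights,
    sample_times = tt * readout_duration,
    readout_duration = readout_duration,
    k0 = k0,
    kmax = kmax,
    t0_fraction = t0_fraction,
    matrix = as.integer(matrix),
    resolution = resolution,
    gamma = 11.262
  ), class = "radial_trajectory")
}

#' Full per-sample k-space coordinates of a trajectory
#'
#' @param traj a \code{radial_trajectory}.
#' @return matrix with one row per sample (spoke-major ordering; sample index
#'   varies fastest) and columns kx, ky, kz in 1/mm.
#' @export
trajectory_coords <- function(traj) {
  stopifnot(inherits(traj, "radial_trajectory"))
  kr <- traj$k_radii
  d <- traj$directions
  cbind(kx = as.vector(outer(kr, d[, 1])),
        ky = as.vector(outer(kr, d[, 2])),
        kz = as.vector(outer(kr, d[, 3])))
}

# Per-sample quantities replicated over spokes (same ordering as
# trajectory_coords).
trajectory_weights <- function(traj) {
  rep(traj$density_weights, times = traj$n_spokes)
}

trajectory_times <- function(traj) {
  rep(traj$sample_times, times = traj$n_spokes)
}

#' @export
print.radial_trajectory <- function(x, ...) {
  cat(sprintf(
    "DA-3DPR trajectory: %d spokes x %d samples, kmax %.4f 1/mm, k0 %.4f 1/mm (t0_fraction %.2f)\n",
    x$n_spokes, x$n_samples_per_spoke, x$kmax, x$k0, x$t0_fraction))
  invisible(x)
}

#' Save / load a trajectory as a named-array container
#'
#' @param traj a \code{radial_trajectory}.
#' @param path file path (.rds).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "radial_trajectory"))
  saveRDS(unclass(traj), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  structure(readRDS(path), class = "radial_trajectory")
}
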