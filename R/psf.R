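# Point-spread-function simulation for the DA-3DPR acquisition.

#' Simulate the point spread function of a radial trajectory
#'
#' The PSF is the reconstruction of unit k-space data: each sample carries
#' value 1, optionally phase-modulated by a constant off-resonance
#' accumulated over the readout and amplitude-modulated by bi-exponential
#' transverse decay during the readout. Small problems can be evaluated with
#' an exact direct Fourier sum; larger grids use the same Kaiser-Bessel
#' gridding operator as \code{\link{grid_reconstruct}}.
#'
#' @param traj a \code{radial_trajectory}.
#' @param grid_size PSF grid size (>= 16 for the gridded path; the main lobe
#'   must fit).
#' @param off_resonance constant off-resonance in Hz applied as
#'   \code{exp(2i pi f t)} over the per-sample readout times.
#' @param method \code{"auto"} (direct sum when the problem is small),
#'   \code{"dft"} (exact direct Fourier sum) or \code{"gridding"}.
#' @param t2s,t2l,fs optional bi-exponential decay during readout (ms, ms,
#'   percent short fraction); \code{NULL} disables decay weighting.
#' @param voxel_size voxel size in mm (default: trajectory resolution).
#' @return object of class \code{psf}: \code{grid} (real 3D array summing to
#'   1), \code{voxel_size}, \code{peak_index}, \code{fwhm} (mm).
#' @export
simulate_psf <- function(traj, grid_size, off_resonance = 0,
                         method = c("auto", "dft", "gridding"),
                         t2s = NULL, t2l = NULL, fs = NULL,
                         voxel_size = NULL) {
  stopifnot(inherits(traj, "radial_trajectory"))
  method <- match.arg(method)
  if (grid_size < 8) stop("grid too small to contain the PSF main lobe")
  if (is.null(voxel_size)) voxel_size <- traj$resolution
  nsamp <- traj$n_spokes * traj$n_samples_per_spoke
  if (method == "auto") {
    method <- if (nsamp * grid_size^3 <= 5e8) "dft" else "gridding"
  }
  tms <- trajectory_times(traj)
  w <- trajectory_weights(traj) *
    exp(2i * pi * off_resonance * tms * 1e-3)
  if (!is.null(t2s)) {
    stopifnot(!is.null(t2l), !is.null(fs))
    w <- w * ((fs / 100) * exp(-tms / t2s) + (1 - fs / 100) * exp(-tms / t2l))
  }
  if (method == "dft") {
    xs <- grid_coords_mm(grid_size, voxel_size)
    xc <- as.matrix(expand.grid(x = xs, y = xs, z = xs))
    vals <- ndft_adjoint(trajectory_coords(traj), as.complex(w), xc)
    grid <- array(Re(vals), dim = rep(grid_size, 3))
  } else {
    if (grid_size < 16) stop("gridded PSF needs grid_size >= 16")
    kb <- .kb_defaults()
    n_os <- kb$os * grid_size
    fov <- grid_size * voxel_size
    units <- .k_to_grid_units(trajectory_coords(traj), fov, n_os, kb$os)
    gr <- kb_grid_adjoint(units, as.complex(w), as.integer(n_os),
                          kb$width, kb$beta)
    dim(gr) <- rep(n_os, 3)
    img <- .crop_center(ifftc(gr), grid_size)
    grid <- Re(.deapodize(img, grid_size, n_os, kb$width, kb$beta))
  }
  total <- sum(grid)
  if (abs(total) < .Machine$double.eps) stop("degenerate PSF (zero sum)")
  grid <- grid / total
  peak <- which(grid == max(grid), arr.ind = TRUE)[1, ]
  ctr <- floor(grid_size / 2) + 1
  if (off_resonance == 0 && any(peak != ctr)) {
    stop("PSF maximum not at grid centre; grid too small or trajectory invalid")
  }
  structure(list(grid = grid, voxel_size = voxel_size,
                 peak_index = peak,
                 fwhm = psf_fwhm(grid, voxel_size)),
            class = "psf")
}

#' Full width at half maximum of a PSF volume
#'
#' Measured along the three axes through the peak with linear interpolation
#' of the half-maximum crossings; the three widths are averaged.
#'
#' @param grid real 3D array (a PSF).
#' @param voxel_size voxel size in mm.
#' @return FWHM in mm.
#' @export
psf_fwhm <- function(grid, voxel_size = 1) {
  pk <- which(grid == max(grid), arr.ind = TRUE)[1, ]
  half <- max(grid) / 2
  axis_width <- function(prof, centre) {
    n <- length(prof)
    # spline-upsample the profile: the main lobe is smooth and linear
    # interpolation on a coarse grid biases the crossing inward
    up <- stats::spline(seq_len(n), prof, n = 50 * n)
    centre_up <- which.min(abs(up$x - centre))
    right <- NA_real_
    for (i in centre_up:(length(up$x) - 1)) {
      if (up$y[i] >= half && up$y[i + 1] < half) {
        right <- up$x[i] + (up$y[i] - half) / (up$y[i] - up$y[i + 1]) *
          (up$x[i + 1] - up$x[i])
        break
      }
    }
    left <- NA_real_
    for (i in centre_up:2) {
      if (up$y[i] >= half && up$y[i - 1] < half) {
        left <- up$x[i] - (up$y[i] - half) / (up$y[i] - up$y[i - 1]) *
          (up$x[i] - up$x[i - 1])
        break
      }
    }
    if (is.na(left) || is.na(right)) {
      stop("grid too small: PSF main lobe does not fall below half maximum")
    }
    right - left
  }
  wx <- axis_width(grid[, pk[2], pk[3]], pk[1])
  wy <- axis_width(grid[pk[1], , pk[3]], pk[2])
  wz <- axis_width(grid[pk[1], pk[2], ], pk[3])
  mean(c(wx, wy, wz)) * voxel_size
}

#' @export
print.psf <- function(x, ...) {
  cat(sprintf("PSF: %s grid, voxel %.2f mm, FWHM %.2f mm\n",
              paste(dim(x$grid), collapse = "x"), x$voxel_size, x$fwhm))
  invisible(x)
}

#' Write a PSF volume as NIfTI
#'
#' @param psf a \code{psf} object.
#' @param path output file path.
#' @export
write_psf_nifti <- function(psf, path) {
  stopifnot(inherits(psf, "psf"))
  img <- RNifti::asNifti(psf$grid)
  RNifti::pixdim(img) <- rep(psf$voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}
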