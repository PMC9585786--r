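# ROI-based T1 (inversion recovery) and bi-exponential T2* relaxometry.

#' Extract per-compartment ROI signal curves from a contrast series
#'
#' The ROI geometry is fixed on the reference contrast (by convention the
#' lowest TE image) and reused unchanged for every other contrast; the mean
#' magnitude signal per compartment and contrast is returned.
#'
#' @param volumes 4D array (x, y, z, contrast) or list of 3D volumes
#'   (complex allowed; magnitudes are taken).
#' @param masks named list of logical 3D arrays, co-registered to the series.
#' @param contrast_values TE or TI values in ms, one per contrast.
#' @param reference_contrast index of the contrast the ROIs were defined on
#'   (default: the lowest contrast value).
#' @return named list of \code{roi_series} objects (\code{roi_label},
#'   \code{contrast_values}, \code{mean_signal}, \code{n_voxels},
#'   \code{reference_contrast}).
#' @export
extract_roi_series <- function(volumes, masks, contrast_values,
                               reference_contrast = which.min(
                                 contrast_values)) {
  if (is.list(volumes)) volumes <- simplify2array(volumes)
  stopifnot(length(dim(volumes)) == 4,
            dim(volumes)[4] == length(contrast_values))
  out <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    nv <- sum(m)
    if (nv == 0) stop(sprintf("empty ROI for compartment '%s'", nm))
    means <- vapply(seq_along(contrast_values), function(ci) {
      mean(Mod(volumes[, , , ci][m]))
    }, numeric(1))
    structure(list(roi_label = nm, contrast_values = contrast_values,
                   mean_signal = means, n_voxels = nv,
                   reference_contrast = reference_contrast),
              class = "roi_series")
  })
  stats::setNames(out, names(masks))
}

# Multi-start bounded Levenberg-Marquardt, returning the best of n_starts
# jittered initializations (fixed sub-seed for reproducibility).
.multistart_lm <- function(resid_fun, par0, lower, upper, n_starts = 8,
                           seed = 42, maxiter = 500, ftol = 1e-10) {
  best <- NULL
  jitters <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      if (i == 1) rep(1, length(par0)) else exp(rnorm(length(par0), 0, 0.4))
    })
  })
  for (j in jitters) {
    p0 <- pmin(pmax(par0 * j, lower + 1e-12), upper - 1e-12)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = ftol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) {
      best <- list(par = fit$par, ssr = ssr,
                   converged = fit$info %in% 1:4)
    }
  }
  best
}

#' Fit the magnitude inversion-recovery T1 model to an ROI curve
#'
#' Model: \code{SI = | Mm (1 - 2 exp(-TI/T1)) | + offset}. The T1 start is
#' taken from the signed-signal null point (\code{TI_null / ln 2}) and the
#' fit is repeated from several jittered starts.
#'
#' @param series an \code{roi_series} with TI contrast values, or a list
#'   with elements \code{contrast_values} and \code{mean_signal}.
#' @param n_starts number of multi-start initializations.
#' @return object of class \code{t1_fit}: \code{mm}, \code{t1} (ms),
#'   \code{offset}, \code{residual_rms}, \code{converged},
#'   \code{degenerate}.
#' @export
fit_t1_ir <- function(series, n_starts = 8) {
  ti <- series$contrast_values
  si <- series$mean_signal
  if (length(unique(ti)) < 4) stop("need at least 4 distinct TI values")
  degenerate <- FALSE
  if (diff(range(si)) < 1e-6 * (mean(abs(si)) + 1e-12)) {
    return(structure(list(mm = NA_real_, t1 = NA_real_,
                          offset = mean(si), residual_rms = 0,
                          converged = FALSE, degenerate = TRUE),
                     class = "t1_fit"))
  }
  t1_init <- max(ti[which.min(si)] / log(2), 1)
  par0 <- c(mm = max(si), t1 = t1_init, offset = max(min(si) / 2, 1e-6))
  model <- function(p, ti) abs(p[1] * (1 - 2 * exp(-ti / p[2]))) + p[3]
  resid_fun <- function(p) model(p, ti) - si
  best <- .multistart_lm(resid_fun, par0,
                         lower = c(0, 0.1, 0), upper = c(Inf, 1e4, Inf),
                         n_starts = n_starts)
  if (is.null(best)) {
    return(structure(list(mm = NA_real_, t1 = NA_real_, offset = NA_real_,
                          residual_rms = NA_real_, converged = FALSE,
                          degenerate = TRUE), class = "t1_fit"))
  }
  p <- best$par
  if (p[2] > 0.99e4 || p[2] <= 0.11) degenerate <- TRUE
  structure(list(mm = unname(p[1]), t1 = unname(p[2]),
                 offset = unname(p[3]),
                 residual_rms = sqrt(best$ssr / length(si)),
                 converged = best$converged && !degenerate,
                 degenerate = degenerate), class = "t1_fit")
}

#' Fit mono- or bi-exponential T2* decay to an ROI curve
#'
#' Bi-exponential model (five parameters):
#' \code{SI = C0s exp(-TE/T2s*) + C0l exp(-TE/T2l*) + offset}, with
#' non-negative amplitudes, relaxation times constrained to
#' \code{[0.1, 100]} ms and ordered \code{T2s* <= T2l*} after fitting.
#' Component fractions are \code{Fs = 100 C0s / (C0s + C0l)} and
#' \code{Fl = 100 - Fs}. A mono-exponential alternative is available for
#' comparison.
#'
#' @param series an \code{roi_series} with TE contrast values.
#' @param model \code{"bi"} (default) or \code{"mono"}.
#' @param n_starts number of multi-start initializations.
#' @return object of class \code{t2star_fit}: \code{c0s}, \code{c0l},
#'   \code{t2s}, \code{t2l}, \code{offset}, \code{fs}, \code{fl},
#'   \code{model}, \code{residual_rms}, \code{converged},
#'   \code{degenerate}.
#' @export
fit_t2star <- function(series, model = c("bi", "mono"), n_starts = 8) {
  model <- match.arg(model)
  te <- series$contrast_values
  si <- series$mean_signal
  need <- if (model == "bi") 7 else 5
  if (length(unique(te)) < need) {
    stop(sprintf("need at least %d distinct TE values for the %s model",
                 need, model))
  }
  amp0 <- max(si) - min(si)
  if (model == "mono") {
    par0 <- c(c0 = amp0, t2 = 8, offset = max(min(si), 1e-6))
    resid_fun <- function(p) p[1] * exp(-te / p[2]) + p[3] - si
    best <- .multistart_lm(resid_fun, par0, lower = c(0, 0.1, 0),
                           upper = c(Inf, 100, Inf), n_starts = n_starts)
    p <- best$par
    return(structure(list(c0s = 0, c0l = unname(p[1]), t2s = NA_real_,
                          t2l = unname(p[2]), offset = unname(p[3]),
                          fs = 0, fl = 100, model = "mono",
                          residual_rms = sqrt(best$ssr / length(si)),
                          converged = best$converged, degenerate = FALSE),
                     class = "t2star_fit"))
  }
  par0 <- c(c0s = 0.6 * amp0, c0l = 0.4 * amp0, t2s = 3, t2l = 13,
            offset = max(min(si), 1e-6))
  resid_fun <- function(p) {
    p[1] * exp(-te / p[3]) + p[2] * exp(-te / p[4]) + p[5] - si
  }
  best <- .multistart_lm(resid_fun, par0, lower = c(0, 0, 0.1, 0.1, 0),
                         upper = c(Inf, Inf, 100, 100, Inf),
                         n_starts = n_starts)
  p <- best$par
  if (p[3] > p[4]) p <- p[c(2, 1, 4, 3, 5)]     # order components
  total <- p[1] + p[2]
  fs <- if (total > 0) unname(100 * p[1] / total) else NA_real_
  degenerate <- abs(p[4] - p[3]) < 0.2 || total == 0 ||
    min(p[1], p[2]) < 1e-3 * total
  structure(list(c0s = unname(p[1]), c0l = unname(p[2]),
                 t2s = unname(p[3]), t2l = unname(p[4]),
                 offset = unname(p[5]), fs = fs, fl = 100 - fs,
                 model = "bi",
                 residual_rms = sqrt(best$ssr / length(si)),
                 converged = best$converged, degenerate = degenerate),
            class = "t2star_fit")
}

#' Relaxometry fit table for a set of ROI series
#'
#' Runs \code{\link{fit_t1_ir}} or \code{\link{fit_t2star}} over compartments
#' and collects the results in a data frame mirroring a per-muscle
#' relaxation-time table.
#'
#' @param roi_list named list of \code{roi_series}.
#' @param type \code{"t1"} or \code{"t2star"}.
#' @return data.frame, one row per compartment.
#' @export
relaxometry_table <- function(roi_list, type = c("t2star", "t1")) {
  type <- match.arg(type)
  rows <- lapply(names(roi_list), function(nm) {
    if (type == "t1") {
      f <- fit_t1_ir(roi_list[[nm]])
      data.frame(muscle = nm, t1 = f$t1, mm = f$mm, offset = f$offset,
                 residual_rms = f$residual_rms, converged = f$converged,
                 degenerate = f$degenerate)
    } else {
      f <- fit_t2star(roi_list[[nm]], model = "bi")
      data.frame(muscle = nm, t2s = f$t2s, t2l = f$t2l, fs = f$fs,
                 fl = f$fl, offset = f$offset,
                 residual_rms = f$residual_rms, converged = f$converged,
                 degenerate = f$degenerate)
    }
  })
  do.call(rbind, rows)
}
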