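# Calibration-curve construction and tissue sodium concentration (TSC).

#' Fit the calibration curve from the tube phantoms
#'
#' Ordinary least-squares line of corrected tube intensity versus known
#' concentration. The reference intensity entering quantification is the
#' curve-predicted corrected intensity at the reference concentration
#' (default 25 mmol/L); a single-tube mode is available by passing one tube.
#'
#' @param tube_means corrected mean intensities, one per tube.
#' @param concentrations known tube concentrations in mmol/L
#'   (default 15.4, 30.8, 46.2, 61.6).
#' @param na_ref reference concentration in mmol/L (default 25).
#' @param force_origin force the line through the origin (default FALSE;
#'   the free intercept absorbs the residual noise floor).
#' @return object of class \code{calibration_curve}: \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{na_ref}, \code{i_phan_corr}
#'   (curve-predicted intensity at \code{na_ref}), plus the input data.
#' @export
fit_calibration_curve <- function(tube_means,
                                  concentrations = c(15.4, 30.8, 46.2, 61.6),
                                  na_ref = 25, force_origin = FALSE) {
  if (length(tube_means) != length(concentrations)) {
    stop("one intensity per concentration required")
  }
  if (length(unique(concentrations)) < 2 && !force_origin) {
    if (length(concentrations) == 1) {
      # single-tube mode: proportional calibration
      slope <- tube_means / concentrations
      if (slope <= 0) stop("non-positive calibration slope")
      return(structure(list(
        concentrations = concentrations, corrected_intensities = tube_means,
        slope = slope, intercept = 0, r_squared = 1, na_ref = na_ref,
        i_phan_corr = slope * na_ref), class = "calibration_curve"))
    }
    stop("need >= 2 distinct concentrations")
  }
  if (force_origin) {
    fit <- lm(tube_means ~ 0 + concentrations)
    slope <- unname(coef(fit)[1])
    intercept <- 0
  } else {
    fit <- lm(tube_means ~ concentrations)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
  }
  if (slope <= 0) {
    stop("non-positive calibration slope: calibration data corrupted")
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((tube_means - mean(tube_means))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(
    concentrations = concentrations,
    corrected_intensities = tube_means,
    slope = slope, intercept = intercept, r_squared = r2,
    na_ref = na_ref,
    i_phan_corr = slope * na_ref + intercept
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "calibration curve: intensity = %.4g x conc %+.4g (r^2 %.4f); I_phan at %.1f mmol/L = %.4g\n",
    x$slope, x$intercept, x$r_squared, x$na_ref, x$i_phan_corr))
  invisible(x)
}

#' Compute tissue sodium concentration per compartment
#'
#' Implements the calibrated ratio
#' \deqn{TSC = \frac{I_{tissue}/f_{tissue}}{I_{phan}/f_{phan}} Na_{ref}}
#' where the intensities have already been corrected for B0/B1
#' inhomogeneity and partial-volume effects, and \code{f} are the
#' relaxation factors of \code{\link{relaxation_factor}} evaluated at the
#' quantification protocol's TR/TE (tissue factors use cohort-mean muscle
#' relaxation values by default; phantom factors the calibration-gel
#' values).
#'
#' @param corrected_means named vector of corrected compartment mean
#'   intensities (e.g. the \code{solved} field of a \code{gtm_system}).
#' @param cal a \code{calibration_curve}.
#' @param tissue_relax data.frame with columns \code{name, t1, t2s, t2l,
#'   fs}, one row per compartment in \code{corrected_means}.
#' @param phantom_relax list/row with \code{t1, t2s, t2l, fs} for the
#'   calibration gel.
#' @param protocol an \code{acquisition_protocol} (its TR and first TE are
#'   used).
#' @return object of class \code{tsc_result}: data.frame with per-compartment
#'   intensity, relaxation factors and \code{tsc} (mmol/L).
#' @export
compute_tsc <- function(corrected_means, cal, tissue_relax, phantom_relax,
                        protocol) {
  stopifnot(inherits(cal, "calibration_curve"))
  nms <- names(corrected_means)
  if (is.null(nms)) stop("corrected_means must be named by compartment")
  idx <- match(nms, tissue_relax$name)
  if (anyNA(idx)) {
    stop(sprintf("missing relaxation parameters for: %s",
                 paste(nms[is.na(idx)], collapse = ", ")))
  }
  tr <- protocol$tr[1]
  te <- protocol$te_list[1]
  ft <- relaxation_factor(tissue_relax$t1[idx], tissue_relax$t2s[idx],
                          tissue_relax$t2l[idx], tissue_relax$fs[idx],
                          tr = tr, te = te)
  fp <- relaxation_factor(phantom_relax$t1, phantom_relax$t2s,
                          phantom_relax$t2l, phantom_relax$fs,
                          tr = tr, te = te)
  means <- as.numeric(corrected_means)
  if (any(means < 0)) {
    warning("negative corrected means clipped to 0")
    means <- pmax(means, 0)
  }
  tsc <- (means / ft) / (cal$i_phan_corr / fp) * cal$na_ref
  structure(list(
    table = data.frame(muscle = nms, i_corr = means,
                       relaxation_factor_tissue = ft,
                       relaxation_factor_phantom = fp,
                       tsc = tsc, row.names = NULL),
    na_ref = cal$na_ref, tr = tr, te = te
  ), class = "tsc_result")
}

#' @export
print.tsc_result <- function(x, ...) {
  cat(sprintf("TSC (Na_ref %.1f mmol/L, TR %.0f ms, TE %.2f ms):\n",
              x$na_ref, x$tr, x$te))
  print(x$table)
  invisible(x)
}

#' Cohort-mean muscle relaxation parameters
#'
#' Per-muscle mean T1, T2* components and short fraction used for
#' relaxation-difference correction (means of the packaged reference
#' relaxometry table, GM/TA/S, with the "other muscle" compartment assigned
#' mid-range values).
#'
#' @return data.frame with columns \code{name, t1, t2s, t2l, fs}.
#' @export
cohort_relaxation_defaults <- function() {
  data.frame(
    name = c("GM", "TA", "S", "other"),
    t1 = c(25.9, 27.6, 28.2, 27.0),
    t2s = c(3.6, 3.2, 3.0, 3.3),
    t2l = c(12.9, 12.8, 12.9, 12.9),
    fs = c(60, 60, 60, 60)
  )
}

#' Calibration-gel relaxation parameters
#'
#' Agarose gel values (T1 matched to muscle by doping, as for the physical
#' calibration tubes).
#'
#' @return list with \code{t1, t2s, t2l, fs}.
#' @export
phantom_relaxation_defaults <- function() {
  list(t1 = 25.0, t2s = 4.0, t2l = 13.0, fs = 60)
}
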