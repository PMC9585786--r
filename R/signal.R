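# Closed-form steady-state and inversion-recovery signal models for 23Na.

# Bi-exponential transverse decay factor at echo time te.
.biexp_te <- function(te, t2s, t2l, fs) {
  (fs / 100) * exp(-te / t2s) + (1 - fs / 100) * exp(-te / t2l)
}

#' Saturation-recovery steady-state sodium signal
#'
#' Forward model underlying both the simulator and the relaxation-difference
#' correction between tissue and calibration phantoms:
#' \deqn{S = TSC \sin(\alpha) (1 - e^{-TR/T1}) [F_s e^{-TE/T2s^*} +
#'   F_l e^{-TE/T2l^*}]}
#' with fractions in percent (\code{fs + fl = 100}).
#'
#' @param tsc sodium concentration, mmol/L.
#' @param t1 longitudinal relaxation time, ms.
#' @param t2s,t2l short/long transverse relaxation times, ms.
#' @param fs short-component fraction, percent.
#' @param tr repetition time, ms.
#' @param te echo time, ms.
#' @param flip_actual actual flip angle in degrees.
#' @return signal in arbitrary units (mmol/L scale at TR >> T1, TE -> 0,
#'   90 degree flip).
#' @export
steady_state_signal <- function(tsc, t1, t2s, t2l, fs, tr, te,
                                flip_actual = 90) {
  stopifnot(all(t1 > 0), all(t2s > 0), all(t2l > 0), all(tr > 0),
            all(te >= 0), all(fs >= 0), all(fs <= 100))
  tsc * sin(flip_actual * pi / 180) * (1 - exp(-tr / t1)) *
    .biexp_te(te, t2s, t2l, fs)
}

#' Signed inversion-recovery sodium signal
#'
#' The saturation factor of \code{\link{steady_state_signal}} is replaced by
#' the inversion-recovery factor \code{(1 - 2 exp(-TI/T1))}; the sign is
#' preserved (magnitude is taken only when images are formed).
#'
#' @inheritParams steady_state_signal
#' @param ti inversion time, ms.
#' @export
ir_signal <- function(tsc, t1, t2s, t2l, fs, ti, te, flip_actual = 90) {
  stopifnot(all(t1 > 0), all(ti >= 0))
  tsc * sin(flip_actual * pi / 180) * (1 - 2 * exp(-ti / t1)) *
    .biexp_te(te, t2s, t2l, fs)
}

#' Relaxation weighting factor for quantification
#'
#' The factor by which measured intensity is attenuated relative to a fully
#' relaxed, zero-TE acquisition:
#' \code{(1 - exp(-TR/T1)) * [Fs exp(-TE/T2s*) + Fl exp(-TE/T2l*)]}.
#' Quantification divides each intensity by its own factor so that tissues
#' and calibration phantoms with different relaxation become comparable.
#'
#' @inheritParams steady_state_signal
#' @return dimensionless factor in (0, 1].
#' @export
relaxation_factor <- function(t1, t2s, t2l, fs, tr, te) {
  stopifnot(all(t1 > 0), all(t2s > 0), all(t2l > 0), all(tr > 0),
            all(te >= 0))
  (1 - exp(-tr / t1)) * .biexp_te(te, t2s, t2l, fs)
}
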