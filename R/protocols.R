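# Acquisition protocol presets and validation.

#' Load an acquisition protocol preset
#'
#' Named presets (\code{"sodium"}, \code{"t2star"}, \code{"t1_ir"},
#' \code{"b0_map"}, \code{"b1_map"}) ship with the package as YAML; the
#' matrix size may be overridden for desk-scale simulation, in which case the
#' number of projections is kept and the simulation voxel size is
#' \code{fov / matrix}.
#'
#' @param name preset name.
#' @param matrix simulation matrix size override (default: preset value).
#' @param fov simulation field of view in mm (default 160).
#' @param n_projections override for the number of radial projections.
#' @param readout_duration per-spoke readout duration in ms (default 10).
#' @return an \code{acquisition_protocol} list with elements \code{tr} (ms;
#'   for IR presets one TR per TI), \code{te_list}, \code{ti_list},
#'   \code{flip_nominal}, \code{matrix}, \code{resolution} (mm),
#'   \code{n_projections}, \code{pulse_duration}, \code{readout_duration}.
#' @export
protocol_preset <- function(name, matrix = NULL, fov = 160,
                            n_projections = NULL, readout_duration = 10) {
  path <- system.file("extdata", "protocols.yaml", package = "natriq")
  presets <- yaml::read_yaml(path)
  if (!name %in% names(presets)) {
    stop(sprintf("unknown protocol preset '%s' (available: %s)", name,
                 paste(names(presets), collapse = ", ")))
  }
  p <- presets[[name]]
  if (is.null(matrix)) matrix <- p$matrix
  ti_list <- if (is.null(p$ti)) numeric(0) else as.numeric(p$ti)
  tr <- as.numeric(p$tr)
  if (length(tr) == 2 && length(ti_list) > 2) {
    # TR range: one TR per TI, linearly spaced
    tr <- seq(tr[1], tr[2], length.out = length(ti_list))
  }
  prot <- structure(list(
    name = name,
    tr = tr,
    te_list = as.numeric(p$te),
    ti_list = ti_list,
    flip_nominal = as.numeric(p$flip),
    matrix = as.integer(matrix),
    resolution = fov / matrix,
    fov = fov,
    nominal_resolution = as.numeric(p$nominal_resolution),
    n_projections = as.integer(
      if (is.null(n_projections)) p$n_projections else n_projections),
    pulse_duration = as.numeric(p$pulse_duration),
    readout_duration = readout_duration
  ), class = "acquisition_protocol")
  validate_protocol(prot)
  prot
}

#' Validate an acquisition protocol
#'
#' Checks the invariants: non-empty increasing TE list and TR exceeding the
#' largest TE.
#'
#' @param prot an \code{acquisition_protocol}.
#' @return the protocol, invisibly.
#' @export
validate_protocol <- function(prot) {
  if (length(prot$te_list) == 0 || any(diff(prot$te_list) <= 0)) {
    stop("te_list must be non-empty and strictly increasing")
  }
  if (any(prot$tr <= max(prot$te_list))) {
    stop("tr must exceed max(te_list)")
  }
  if (length(prot$ti_list) > 0 && any(prot$ti_list < 0)) {
    stop("inversion times must be non-negative")
  }
  invisible(prot)
}

# Trajectory for a protocol on the simulation grid.
protocol_trajectory <- function(prot, t0_fraction = 0.25) {
  build_da3dpr_trajectory(prot$n_projections, prot$matrix, prot$resolution,
                          t0_fraction = t0_fraction,
                          readout_duration = prot$readout_duration)
}
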