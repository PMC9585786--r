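# Digital calf phantom: schematic multi-compartment geometry with known
# concentrations, relaxation parameters and smooth B0/B1/coil fields.

.LABELS <- c(background = 0L, GM = 1L, TA = 2L, S = 3L, other = 4L,
             tube1 = 5L, tube2 = 6L, tube3 = 7L, tube4 = 8L, cylinder = 9L)

.TUBE_CONC <- c(15.4, 30.8, 46.2, 61.6)

# Per-label true parameters for a scenario. Muscle relaxation values are the
# healthy-cohort means; agarose tubes/cylinder are T1-matched to muscle.
.label_params <- function(scenario) {
  tsc_muscle <- switch(scenario,
    healthy    = c(GM = 19.9, TA = 13.8, S = 12.6, other = 15.0),
    addison    = c(GM = 10.2, TA = 8.4, S = 7.2, other = 8.0),
    cylinder   = c(GM = 0, TA = 0, S = 0, other = 0),
    tubes_only = c(GM = 0, TA = 0, S = 0, other = 0))
  data.frame(
    label = unname(.LABELS),
    name = names(.LABELS),
    tsc = c(0, tsc_muscle[["GM"]], tsc_muscle[["TA"]], tsc_muscle[["S"]],
            tsc_muscle[["other"]], .TUBE_CONC, 61.6),
    t1  = c(Inf, 25.9, 27.6, 28.2, 27.0, rep(25.0, 4), 25.0),
    t2s = c(Inf, 3.6, 3.2, 3.0, 3.3, rep(4.0, 4), 4.0),
    t2l = c(Inf, 12.9, 12.8, 12.9, 12.9, rep(13.0, 4), 13.0),
    fs  = c(0, rep(60, 4), rep(60, 4), 60),
    row.names = NULL
  )
}

# Geometry in mm for a 160 mm reference FOV; scaled linearly for other FOVs.
.phantom_geometry <- function(fov) {
  u <- fov / 160
  list(
    unit = u,
    calf = list(cx = 0, cy = 0, a = 46 * u, b = 40 * u),
    gm   = list(cx = 0, cy = -22 * u, a = 27 * u, b = 13 * u),
    ta   = list(cx = 0, cy = 30 * u, a = 26 * u, b = 9 * u),
    sol  = list(cx = 0, cy = 10 * u, a = 30 * u, b = 15 * u),
    tube_ring_radius = 62 * u,
    tube_radius = 12 * u,
    tube_angles = c(45, 135, 225, 315) * pi / 180,
    cylinder_radius = 76 * u,
    z_half_extent = 0.8 * fov / 2
  )
}

.in_ellipse <- function(X, Y, e) {
  ((X - e$cx) / e$a)^2 + ((Y - e$cy) / e$b)^2 <= 1
}

#' Generate a digital calf phantom
#'
#' Builds a schematic, extruded-2D digital phantom of the lower leg: an
#' elliptical calf cross-section containing three muscle compartments
#' (gastrocnemius medialis, tibialis anterior, soleus) embedded in "other
#' muscle", four peripheral calibration tubes at 15.4/30.8/46.2/61.6 mmol/L,
#' and smooth low-order B0 (Hz) and B1+ (relative flip) fields plus complex
#' coil sensitivity profiles. The \code{"cylinder"} scenario replaces the
#' anatomy with a single homogeneous 61.6 mmol/L cylinder filling the coil,
#' as used for field mapping and intensity-correction derivation.
#'
#' @param matrix isotropic matrix size (>= 32).
#' @param scenario \code{"healthy"}, \code{"addison"}, \code{"cylinder"} or
#'   \code{"tubes_only"}.
#' @param seed integer seed recorded for provenance (the phantom itself is
#'   deterministic).
#' @param fov field of view in mm (default 160, i.e. 2.5 mm voxels at 64).
#' @param n_coils number of receive coils (>= 1).
#' @return object of class \code{digital_phantom}: \code{labels} (integer 3D
#'   array), \code{label_table} (per-label true TSC and relaxation
#'   parameters), \code{b0_map}, \code{b1_map}, \code{coil_sens} (list of
#'   complex arrays), \code{voxel_size}, \code{geometry}.
#' @export
make_digital_phantom <- function(matrix = 64,
                                 scenario = c("healthy", "addison",
                                              "cylinder", "tubes_only"),
                                 seed = 20220719, fov = 160, n_coils = 2) {
  scenario <- match.arg(scenario)
  if (matrix < 32) stop("matrix must be >= 32")
  n <- as.integer(matrix)
  voxel <- fov / n
  g <- .phantom_geometry(fov)
  xs <- grid_coords_mm(n, voxel)
  X <- array(rep(xs, times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(xs, each = n), times = n), dim = c(n, n, n))
  Z <- array(rep(xs, each = n * n), dim = c(n, n, n))
  in_z <- abs(Z) <= g$z_half_extent

  labels <- array(.LABELS[["background"]], dim = c(n, n, n))
  if (scenario == "cylinder") {
    labels[(X^2 + Y^2 <= g$cylinder_radius^2) & in_z] <- .LABELS[["cylinder"]]
  } else {
    if (scenario != "tubes_only") {
      calf <- .in_ellipse(X, Y, g$calf) & in_z
      labels[calf] <- .LABELS[["other"]]
      gm <- .in_ellipse(X, Y, g$gm) & calf
      labels[gm] <- .LABELS[["GM"]]
      ta <- .in_ellipse(X, Y, g$ta) & calf & labels == .LABELS[["other"]]
      labels[ta] <- .LABELS[["TA"]]
      sol <- .in_ellipse(X, Y, g$sol) & calf & labels == .LABELS[["other"]]
      labels[sol] <- .LABELS[["S"]]
    }
    for (k in seq_len(4)) {
      tx <- g$tube_ring_radius * cos(g$tube_angles[k])
      ty <- g$tube_ring_radius * sin(g$tube_angles[k])
      tube <- ((X - tx)^2 + (Y - ty)^2 <= g$tube_radius^2) & in_z
      labels[tube] <- .LABELS[[paste0("tube", k)]]
    }
  }

  R <- fov / 2
  rho2 <- (X^2 + Y^2) / R^2
  b0_map <- 25 * X / R + 15 * Y / R + 10 * (rho2 - 0.5)
  b1_map <- 1.2 - 0.4 * pmin(rho2, 1)

  coil_sens <- lapply(seq_len(n_coils), function(k) {
    sgn <- if (k %% 2 == 1) 1 else -1
    mag <- (1.15 - 0.35 * pmin(rho2, 1)) * (1 + 0.12 * sgn * X / R)
    ph <- 0.3 * sgn * (X + 0.5 * Y) / R
    mag * exp(1i * ph)
  })

  structure(list(
    labels = labels,
    label_table = .label_params(scenario),
    b0_map = b0_map,
    b1_map = b1_map,
    coil_sens = coil_sens,
    voxel_size = voxel,
    fov = fov,
    matrix = n,
    scenario = scenario,
    seed = as.integer(seed),
    geometry = g
  ), class = "digital_phantom")
}

#' Binary compartment masks of a phantom
#'
#' @param ph a \code{digital_phantom}.
#' @param names label names to extract (default: the four muscle
#'   compartments plus background).
#' @return named list of logical 3D arrays (pairwise disjoint).
#' @export
phantom_masks <- function(ph, names = c("GM", "TA", "S", "other",
                                        "background")) {
  stopifnot(inherits(ph, "digital_phantom"))
  out <- lapply(names, function(nm) ph$labels == .LABELS[[nm]])
  stats::setNames(out, names)
}

#' Eroded calibration-tube ROIs
#'
#' Calibration intensities are read from ROIs drawn inside each tube, kept
#' away from the tube wall so that partial-volume blurring at the edge does
#' not bias the calibration curve (the tubes deliberately bypass the GTM
#' correction).
#'
#' @param ph a \code{digital_phantom} containing tubes.
#' @param margin_mm margin eroded from the tube radius (default 5 mm).
#' @return named list of logical arrays \code{tube1..tube4}.
#' @export
calibration_tube_rois <- function(ph, margin_mm = 5) {
  stopifnot(inherits(ph, "digital_phantom"))
  g <- ph$geometry
  n <- ph$matrix
  xs <- grid_coords_mm(n, ph$voxel_size)
  X <- array(rep(xs, times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(xs, each = n), times = n), dim = c(n, n, n))
  Z <- array(rep(xs, each = n * n), dim = c(n, n, n))
  r <- g$tube_radius - margin_mm
  if (r <= ph$voxel_size) stop("margin leaves no tube interior")
  in_z <- abs(Z) <= g$z_half_extent - margin_mm
  out <- lapply(seq_len(4), function(k) {
    tx <- g$tube_ring_radius * cos(g$tube_angles[k])
    ty <- g$tube_ring_radius * sin(g$tube_angles[k])
    ((X - tx)^2 + (Y - ty)^2 <= r^2) & in_z
  })
  stats::setNames(out, paste0("tube", seq_len(4)))
}

#' Per-label lookup of a parameter as a voxel map
#'
#' @param ph a \code{digital_phantom}.
#' @param param column of the label table (\code{"tsc"}, \code{"t1"}, ...).
#' @return numeric 3D array.
#' @export
phantom_param_map <- function(ph, param = "tsc") {
  stopifnot(inherits(ph, "digital_phantom"))
  lut <- ph$label_table[[param]][match(ph$labels, ph$label_table$label)]
  array(lut, dim = dim(ph$labels))
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf("digital calf phantom: scenario '%s', %d^3 at %.2f mm, %d coil(s)\n",
              x$scenario, x$matrix, x$voxel_size, length(x$coil_sens)))
  invisible(x)
}

#' Export a phantom as NIfTI volumes with a JSON sidecar
#'
#' Writes label map, B0 and B1 fields (NIfTI) and a JSON sidecar holding the
#' label table, scenario, seed and geometry.
#'
#' @param ph a \code{digital_phantom}.
#' @param prefix output path prefix.
#' @return invisibly, the written file paths.
#' @export
write_phantom_nifti <- function(ph, prefix) {
  stopifnot(inherits(ph, "digital_phantom"))
  pd <- rep(ph$voxel_size, 3)
  paths <- c(
    labels = paste0(prefix, "_labels.nii"),
    b0 = paste0(prefix, "_b0.nii"),
    b1 = paste0(prefix, "_b1.nii"),
    sidecar = paste0(prefix, ".json"))
  write_one <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- pd
    RNifti::writeNifti(img, path)
  }
  write_one(ph$labels + 0, paths[["labels"]])
  write_one(ph$b0_map, paths[["b0"]])
  write_one(ph$b1_map, paths[["b1"]])
  sidecar <- list(scenario = ph$scenario, seed = ph$seed,
                  voxel_size = ph$voxel_size, fov = ph$fov,
                  matrix = ph$matrix, label_table = ph$label_table)
  jsonlite::write_json(sidecar, paths[["sidecar"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
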