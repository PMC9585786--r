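# Geometric-transfer-matrix (GTM) partial-volume correction.

#' Region-spread function of a compartment mask
#'
#' Convolution of the binary mask with the normalized PSF. By default the
#' convolution is zero-padded to avoid wrap-around; \code{circular = TRUE}
#' performs the convolution on the periodic reconstruction grid (consistent
#' with gridding reconstruction, whose PSF is itself periodic).
#'
#' @param mask logical/numeric 3D array.
#' @param psf a \code{psf} object, a real 3D kernel array, or a linear
#'   imaging-operator function as built by \code{\link{psf_operator}} (in
#'   which case the RSF is the operator applied to the mask, exactly
#'   matching the reconstruction's blur).
#' @param circular use circular convolution on the mask grid (default FALSE).
#' @return real 3D array, same dimensions as \code{mask}.
#' @export
compute_rsf <- function(mask, psf, circular = FALSE) {
  if (is.function(psf)) return(Re(psf(mask + 0)))
  kern <- if (inherits(psf, "psf")) psf$grid else psf
  s <- sum(kern)
  if (abs(s - 1) > 1e-8) {
    message("PSF not normalized; normalizing to unit sum")
    kern <- kern / s
  }
  m <- mask + 0
  dm <- dim(m)
  dk <- dim(kern)
  pk <- which(kern == max(kern), arr.ind = TRUE)[1, ]
  if (circular) {
    if (!all(dm == dk)) stop("circular convolution needs matching grids")
    out <- Re(fft(fft(m) * fft(circshift(kern, -(pk - 1))),
                  inverse = TRUE)) / prod(dm)
    return(out)
  }
  dp <- dm + dk
  mp <- array(0, dp)
  mp[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- m
  kp <- array(0, dp)
  kp[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kern
  kp <- circshift(kp, -(pk - 1))
  conv <- Re(fft(fft(mp) * fft(kp), inverse = TRUE)) / prod(dp)
  conv[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])]
}

#' GTM partial-volume correction of compartment means
#'
#' Assembles the geometric transfer matrix \code{w[j, i] = mean over ROI j
#' of RSF_i} from the region-spread functions of all compartments, measures
#' the observed ROI means \code{b} of the image, and solves \code{w c = b}
#' by least squares for the partial-volume-corrected compartment means
#' \code{c}. Compartments that are not explicitly segmented should be
#' absorbed into an "other"/background compartment so that the rows of
#' \code{w} sum to ~1.
#'
#' @param masks named list of >= 2 pairwise-disjoint logical 3D arrays.
#' @param psf a \code{psf} object, kernel array (normalized internally), or
#'   imaging-operator function (see \code{\link{compute_rsf}}).
#' @param image real 3D array on the mask grid.
#' @param circular passed to \code{\link{compute_rsf}}.
#' @param max_condition condition-number threshold beyond which the system
#'   is rejected (default 1e6).
#' @return object of class \code{gtm_system}: \code{weights} (n x n),
#'   \code{observed}, \code{solved}, \code{condition_number},
#'   \code{compartments}.
#' @export
gtm_correct <- function(masks, psf, image, circular = FALSE,
                        max_condition = 1e6) {
  if (length(masks) < 2) stop("need at least 2 compartments")
  if (!all(dim(image) == dim(masks[[1]]))) {
    stop("image must be on the mask grid")
  }
  nms <- names(masks)
  n <- length(masks)
  rsfs <- lapply(masks, compute_rsf, psf = psf, circular = circular)
  w <- matrix(0, n, n, dimnames = list(roi = nms, rsf = nms))
  b <- numeric(n)
  for (j in seq_len(n)) {
    mj <- masks[[j]]
    if (!any(mj)) stop(sprintf("compartment '%s' is empty", nms[j]))
    for (i in seq_len(n)) w[j, i] <- mean(rsfs[[i]][mj])
    b[j] <- mean(image[mj])
  }
  cond <- kappa(w, exact = TRUE)
  if (cond > max_condition) {
    stop(sprintf(
      "GTM system ill-conditioned (condition number %.3g); consider merging compartments",
      cond))
  }
  solved <- qr.solve(w, b)
  structure(list(weights = w, observed = stats::setNames(b, nms),
                 solved = stats::setNames(solved, nms),
                 condition_number = cond, compartments = nms),
            class = "gtm_system")
}

#' @export
print.gtm_system <- function(x, ...) {
  cat("GTM system (condition number", format(x$condition_number, digits = 4),
      ")\n")
  print(data.frame(compartment = x$compartments, observed = x$observed,
                   solved = x$solved, row.names = NULL))
  invisible(x)
}

#' Dump a GTM system as CSV for audit
#'
#' @param gtm a \code{gtm_system}.
#' @param path output CSV path.
#' @export
write_gtm_csv <- function(gtm, path) {
  stopifnot(inherits(gtm, "gtm_system"))
  df <- as.data.frame(gtm$weights)
  df$observed <- gtm$observed
  df$solved <- gtm$solved
  utils::write.csv(cbind(compartment = gtm$compartments, df), path,
                   row.names = FALSE)
  invisible(path)
}
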