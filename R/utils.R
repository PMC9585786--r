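# Internal helpers shared across modules.

#' @useDynLib natriq, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft rnorm coef lm median sd var approx pf qf setNames
#' @importFrom utils head tail read.csv write.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Circular shift of an n-dimensional array by `shift` (vector, one per dim).
circshift <- function(x, shift) {
  d <- dim(x)
  if (is.null(d)) {
    n <- length(x)
    return(x[((seq_len(n) - 1 - shift) %% n) + 1])
  }
  idx <- lapply(seq_along(d), function(i) {
    ((seq_len(d[i]) - 1 - shift[i]) %% d[i]) + 1
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Centered FFT conventions: object/DC at index floor(n/2)+1 of each axis.
fftc <- function(x) {
  d <- dim(x)
  circshift(fft(circshift(x, -floor(d / 2))), floor(d / 2))
}

ifftc <- function(x) {
  d <- dim(x)
  circshift(fft(circshift(x, -floor(d / 2)), inverse = TRUE), floor(d / 2)) /
    prod(d)
}

# Complex Gaussian noise array, sd per real/imaginary channel.
complex_noise <- function(dim, sigma) {
  array(complex(real = rnorm(prod(dim), sd = sigma),
                imaginary = rnorm(prod(dim), sd = sigma)), dim = dim)
}

# 1D convolution with edge replication (kernel must be odd-length).
conv1_replicate <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  xp <- c(rep(x[1], r), x, rep(x[length(x)], r))
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(r + 1L):(r + length(x))])
}

# Separable 3D Gaussian smoothing with edge replication.
gauss_smooth3 <- function(arr, sd) {
  if (sd <= 0) return(arr)
  r <- max(1L, ceiling(3 * sd))
  k <- exp(-((-r):r)^2 / (2 * sd^2))
  k <- k / sum(k)
  d <- dim(arr)
  for (ax in 1:3) {
    arr <- aperm(arr, c(ax, setdiff(1:3, ax)))
    da <- dim(arr)
    arr <- array(apply(arr, 2:3, conv1_replicate, k = k), dim = da)
    arr <- aperm(arr, order(c(ax, setdiff(1:3, ax))))
  }
  array(arr, dim = d)
}

# Coordinate grids (mm) for a cubic volume centred at the FOV centre.
grid_coords_mm <- function(n, voxel) {
  (seq_len(n) - 1 - floor(n / 2)) * voxel
}

# Root-mean-square helper.
rms <- function(x) sqrt(mean(Mod(x)^2))
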