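# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's gridding/convolution/DP code paths.

# Direct conjugate-phase adjoint: sum_j data_j w_j exp(+2 pi i k_j . x) on a
# centred cubic grid (chunked matrix products; plain R).
oracle_ndft_adjoint <- function(coords, weights, data, n, voxel) {
  xs <- (seq_len(n) - 1 - floor(n / 2)) * voxel
  xg <- as.matrix(expand.grid(xs, xs, xs))
  out <- complex(length.out = n^3)
  ns <- nrow(coords)
  step <- 4000
  for (s in seq(1, ns, by = step)) {
    e <- s:min(s + step - 1, ns)
    ph <- xg %*% t(coords[e, , drop = FALSE])
    out <- out + (exp(2i * pi * ph) %*% (weights[e] * data[e]))[, 1]
  }
  array(out, dim = c(n, n, n))
}

# Direct forward: sum_x img_x exp(-2 pi i k_j . x).
oracle_ndft_forward <- function(img, coords, voxel) {
  n <- dim(img)[1]
  xs <- (seq_len(n) - 1 - floor(n / 2)) * voxel
  xg <- as.matrix(expand.grid(xs, xs, xs))
  iv <- as.vector(img)
  ns <- nrow(coords)
  out <- complex(length.out = ns)
  step <- 4000
  for (s in seq(1, ns, by = step)) {
    e <- s:min(s + step - 1, ns)
    ph <- xg %*% t(coords[e, , drop = FALSE])
    out[e] <- colSums(iv * exp(-2i * pi * ph))
  }
  out
}

# Spatial-domain convolution by explicit kernel loop (kernel peak-centred).
oracle_conv3 <- function(mask, kern) {
  dm <- dim(mask)
  dk <- dim(kern)
  pk <- which(kern == max(kern), arr.ind = TRUE)[1, ]
  out <- array(0, dm)
  m <- mask + 0
  for (i in seq_len(dk[1])) {
    for (j in seq_len(dk[2])) {
      for (l in seq_len(dk[3])) {
        kv <- kern[i, j, l]
        if (kv == 0) next
        sx <- i - pk[1]; sy <- j - pk[2]; sz <- l - pk[3]
        xs <- seq_len(dm[1]) + sx
        ys <- seq_len(dm[2]) + sy
        zs <- seq_len(dm[3]) + sz
        okx <- xs >= 1 & xs <= dm[1]
        oky <- ys >= 1 & ys <= dm[2]
        okz <- zs >= 1 & zs <= dm[3]
        out[xs[okx], ys[oky], zs[okz]] <-
          out[xs[okx], ys[oky], zs[okz]] +
          kv * m[which(okx), which(oky), which(okz)]
      }
    }
  }
  out
}

# Exact signed-rank two-sided p by enumerating all 2^n sign assignments.
oracle_signed_rank_exact <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  p_low <- mean(vs <= v_obs)
  p_high <- mean(vs >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# Exact rank-sum two-sided p by enumerating all group assignments.
oracle_rank_sum_exact <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(pooled), n1)
  ws <- apply(sets, 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Exact Friedman p by enumerating all k!^n within-subject permutations
# (n small).
oracle_friedman_exact <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  ranks <- t(apply(mat, 1, rank))
  stat <- function(cs) 12 / (n * k * (k + 1)) * sum(cs^2) - 3 * n * (k + 1)
  obs <- stat(colSums(ranks))
  perms <- gtools_perms(k)
  idx <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), n)))
  cnt <- 0
  for (r in seq_len(nrow(idx))) {
    cs <- numeric(k)
    for (s in seq_len(n)) cs <- cs + ranks[s, perms[idx[r, s], ]]
    if (stat(cs) >= obs - 1e-9) cnt <- cnt + 1
  }
  cnt / nrow(idx)
}

# All permutations of 1..k as rows (tiny k).
gtools_perms <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- gtools_perms(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  unname(out)
}

# ICC variants from aov() mean squares (independent of the package's sums
# of squares).
oracle_icc_aov <- function(mat, variant) {
  n <- nrow(mat)
  k <- ncol(mat)
  df <- data.frame(y = as.vector(mat),
                   subj = factor(rep(seq_len(n), k)),
                   sess = factor(rep(seq_len(k), each = n)))
  a <- anova(lm(y ~ subj + sess, data = df))
  msr <- a["subj", "Mean Sq"]
  msc <- a["sess", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  switch(variant,
    A1 = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
    Ak = (msr - mse) / (msr + (msc - mse) / n),
    C1 = (msr - mse) / (msr + (k - 1) * mse),
    Ck = 1 - mse / msr)
}

# Centred sphere mask and coordinate arrays.
make_coords <- function(n, voxel) {
  xs <- (seq_len(n) - 1 - floor(n / 2)) * voxel
  list(
    x = array(rep(xs, times = n * n), c(n, n, n)),
    y = array(rep(rep(xs, each = n), times = n), c(n, n, n)),
    z = array(rep(xs, each = n * n), c(n, n, n)))
}
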