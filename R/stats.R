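# Repeatability statistics: two-way ICC, Bland-Altman agreement, and exact
# nonparametric tests (Friedman, Wilcoxon signed-rank and rank-sum).

# Two-way (subjects x sessions) ANOVA mean squares.
.twoway_ms <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  grand <- mean(mat)
  rowm <- rowMeans(mat)
  colm <- colMeans(mat)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Two-way intraclass correlation coefficient
#'
#' ICC from the two-way (subjects x sessions) ANOVA decomposition, in four
#' variants: absolute-agreement single/average measures (\code{A1},
#' \code{Ak}) and consistency single/average measures (\code{C1},
#' \code{Ck}). 95\% confidence intervals follow the F-distribution formulas
#' of the standard two-way model (exact for the consistency variants,
#' Satterthwaite approximation for absolute agreement).
#'
#' @param table data.frame in long format with columns \code{subject},
#'   \code{session}, \code{tsc} (one muscle at a time), or a complete
#'   numeric matrix (subjects x sessions).
#' @param variant one of \code{"A1"}, \code{"Ak"}, \code{"C1"}, \code{"Ck"}.
#' @param conf confidence level (default 0.95).
#' @return object of class \code{icc_result}: \code{variant}, \code{value},
#'   \code{ci_low}, \code{ci_high}, mean squares \code{msr}, \code{msc},
#'   \code{mse}, \code{n_subjects}, \code{k_sessions}.
#' @export
icc_twoway <- function(table, variant = c("Ck", "A1", "Ak", "C1"),
                       conf = 0.95) {
  variant <- match.arg(variant)
  if (is.data.frame(table)) {
    mat <- tapply(table$tsc, list(table$subject, table$session), mean)
    if (anyNA(mat)) stop("incomplete subject x session matrix (no imputation)")
  } else {
    mat <- as.matrix(table)
    if (anyNA(mat)) stop("incomplete subject x session matrix (no imputation)")
  }
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 sessions")
  ms <- .twoway_ms(mat)
  msr <- ms$msr; msc <- ms$msc; mse <- ms$mse
  value <- switch(variant,
    A1 = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
    Ak = (msr - mse) / (msr + (msc - mse) / n),
    C1 = (msr - mse) / (msr + (k - 1) * mse),
    Ck = 1 - mse / msr)
  alpha <- 1 - conf
  dfr <- n - 1
  dfe <- (n - 1) * (k - 1)
  if (variant %in% c("C1", "Ck")) {
    fobs <- msr / mse
    fl <- fobs / qf(1 - alpha / 2, dfr, dfe)
    fu <- fobs * qf(1 - alpha / 2, dfe, dfr)
    if (variant == "C1") {
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    } else {
      ci <- c(1 - 1 / fl, 1 - 1 / fu)
    }
  } else {
    # Satterthwaite-style CI for absolute agreement (McGraw & Wong)
    a <- (k * value) / (n * (1 - value))
    b <- 1 + (k * value * (n - 1)) / (n * (1 - value))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / dfe)
    fstar <- qf(1 - alpha / 2, dfr, v)
    fstar2 <- qf(1 - alpha / 2, v, dfr)
    fj <- msr / (a * msc + b * mse) # observed F for A-type
    low1 <- (n * (msr - fstar * mse)) /
      (fstar * (k * msc + (k * n - k - n) * mse) + n * msr)
    up1 <- (n * (fstar2 * msr - mse)) /
      (k * msc + (k * n - k - n) * mse + n * fstar2 * msr)
    if (variant == "A1") {
      ci <- c(low1, up1)
    } else {
      ci <- c(k * low1 / (1 + (k - 1) * low1), k * up1 / (1 + (k - 1) * up1))
    }
  }
  structure(list(variant = variant, value = value,
                 ci_low = min(ci), ci_high = max(ci),
                 msr = msr, msc = msc, mse = mse,
                 n_subjects = n, k_sessions = k), class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s) = %.3f (95%% CI %.3f-%.3f); n=%d, k=%d\n",
              x$variant, x$value, x$ci_low, x$ci_high, x$n_subjects,
              x$k_sessions))
  invisible(x)
}

#' Bland-Altman agreement between two sessions
#'
#' Per-subject differences between two measurement sessions; limits of
#' agreement are \code{mean(diff) +/- 1.96 sd(diff)}.
#'
#' @param table long-format data.frame with columns \code{subject},
#'   \code{session}, \code{muscle}, \code{tsc}.
#' @param muscle muscle to analyse.
#' @param session_pair character vector of two session labels.
#' @return object of class \code{agreement_result}: \code{pair},
#'   \code{mean_diff}, \code{sd_diff}, \code{loa_low}, \code{loa_high},
#'   \code{fraction_within}, \code{differences}, \code{averages}.
#' @export
bland_altman <- function(table, muscle, session_pair) {
  stopifnot(length(session_pair) == 2)
  sub <- table[table$muscle == muscle & table$session %in% session_pair, ]
  wide <- tapply(sub$tsc, list(sub$subject, sub$session), mean)
  wide <- wide[, session_pair, drop = FALSE]
  if (anyNA(wide)) stop("both sessions must be present for every subject")
  if (nrow(wide) < 3) stop("need at least 3 subjects")
  d <- wide[, 1] - wide[, 2]
  avg <- rowMeans(wide)
  m <- mean(d)
  s <- sd(d)
  loa <- c(m - 1.96 * s, m + 1.96 * s)
  structure(list(pair = paste(session_pair, collapse = "-vs-"),
                 muscle = muscle, mean_diff = m, sd_diff = s,
                 loa_low = loa[1], loa_high = loa[2],
                 fraction_within = mean(d >= loa[1] & d <= loa[2]),
                 differences = unname(d), averages = unname(avg)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman %s (%s): mean diff %.3f, LoA [%.3f, %.3f], %.0f%% within\n",
    x$muscle, x$pair, x$mean_diff, x$loa_low, x$loa_high,
    100 * x$fraction_within))
  invisible(x)
}

# --- exact nonparametric tests --------------------------------------------

# Midranks scaled by 2 so that tied midranks become integers.
.int_ranks2 <- function(x) {
  r2 <- round(2 * rank(x))
  if (max(abs(r2 - 2 * rank(x))) > 1e-9) stop("non-half-integer midranks")
  as.integer(r2)
}

#' Friedman test across k related conditions
#'
#' Classic rank statistic with midranks for ties:
#' \code{chi2 = 12/(n k (k+1)) sum R_j^2 - 3 n (k+1)}. The exact permutation
#' p-value enumerates, via dynamic programming over subjects, all
#' within-subject orderings (equivalent to full enumeration of the
#' \code{k!^n} permutations); the asymptotic chi-square p-value is also
#' reported.
#'
#' @param mat numeric matrix, subjects in rows, conditions in columns (e.g.
#'   one column per muscle, one row per subject).
#' @param mode \code{"exact"} (default for n <= 15) or \code{"asymptotic"}.
#' @return object of class \code{test_result} with \code{statistic},
#'   \code{p_exact}, \code{p_asymptotic}, \code{n}.
#' @export
friedman_test <- function(mat, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  mat <- as.matrix(mat)
  n <- nrow(mat)
  k <- ncol(mat)
  stopifnot(n >= 2, k >= 2)
  ranks <- t(apply(mat, 1, rank))
  stat_from_colsums <- function(cs) {
    12 / (n * k * (k + 1)) * sum(cs^2) - 3 * n * (k + 1)
  }
  cs_obs <- colSums(ranks)
  statistic <- stat_from_colsums(cs_obs)
  p_asym <- stats::pchisq(statistic, df = k - 1, lower.tail = FALSE)
  do_exact <- (mode == "exact") || (mode == "auto" && n <= 15 && k <= 4)
  p_exact <- NA_real_
  if (do_exact) {
    # DP over subjects on the joint distribution of column rank sums
    # (doubled to keep tied midranks integral); equivalent to enumerating
    # all k!^n within-subject permutations.
    ranks2 <- 2 * ranks
    key <- function(v) paste(v, collapse = ",")
    cur <- setNames(list(1), key(integer(k - 1)))
    for (s in seq_len(n)) {
      perms <- unique(.perms(ranks2[s, ]))
      nxt <- new.env(hash = TRUE)
      for (ky in names(cur)) {
        base <- as.integer(strsplit(ky, ",")[[1]])
        for (pi in seq_len(nrow(perms))) {
          nk <- key(base + perms[pi, seq_len(k - 1)])
          prev <- if (exists(nk, envir = nxt, inherits = FALSE)) {
            get(nk, envir = nxt)
          } else 0
          assign(nk, prev + cur[[ky]] / nrow(perms), envir = nxt)
        }
      }
      cur <- as.list(nxt)
    }
    grand2 <- sum(ranks2)              # total doubled rank mass, all columns
    p_exact <- 0
    for (ky in names(cur)) {
      cs2 <- as.integer(strsplit(ky, ",")[[1]])
      cs_all <- c(cs2, grand2 - sum(cs2)) / 2
      st <- stat_from_colsums(cs_all)
      if (st >= statistic - 1e-9) p_exact <- p_exact + cur[[ky]]
    }
  }
  structure(list(method = "friedman", statistic = statistic,
                 p_exact = p_exact, p_asymptotic = p_asym,
                 correction = "none", n = n, k = k),
            class = "test_result")
}

# All distinct permutations of a small vector (k <= 4), as rows.
.perms <- function(v) {
  k <- length(v)
  if (k == 1) return(matrix(v, 1))
  out <- NULL
  for (i in seq_len(k)) {
    rest <- .perms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  unique(out)
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; ties among the absolute differences take
#' midranks. The exact two-sided p-value is computed from the full
#' distribution of the positive-rank sum over all 2^n sign assignments
#' (evaluated by generating-function convolution, identical to brute-force
#' enumeration). An optional Bonferroni correction multiplies the p-value
#' by \code{m_comparisons}, capped at 1.
#'
#' @param x,y paired numeric vectors.
#' @param mode \code{"exact"} (default for n <= 25) or \code{"asymptotic"}.
#' @param m_comparisons Bonferroni multiplier (default 1).
#' @return \code{test_result} with \code{statistic} (positive-rank sum V),
#'   \code{p_exact}, \code{p_asymptotic}, \code{p} (corrected, preferred
#'   mode), \code{n} (nonzero pairs).
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("auto", "exact",
                                                "asymptotic"),
                                 m_comparisons = 1) {
  mode <- match.arg(mode)
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(method = "signed_rank", statistic = 0,
                          p_exact = 1, p_asymptotic = 1, p = 1,
                          correction = if (m_comparisons > 1) "bonferroni"
                          else "none", n = 0), class = "test_result"))
  }
  r2 <- .int_ranks2(abs(d))            # doubled midranks (integers)
  v2 <- sum(r2[d > 0])                 # doubled statistic
  tot2 <- sum(r2)
  # distribution of the doubled positive-rank sum over 2^n sign choices
  pmf <- c(1)                           # index i -> value i-1
  for (ri in r2) {
    shifted <- c(rep(0, ri), pmf)
    pmf <- c(pmf, rep(0, ri)) + shifted
  }
  pmf <- pmf / 2^n
  vals <- seq_along(pmf) - 1
  p_low <- sum(pmf[vals <= v2])
  p_high <- sum(pmf[vals >= v2])
  p_exact <- min(1, 2 * min(p_low, p_high))
  # normal approximation with tie correction
  mu <- tot2 / 2 / 2
  ties <- table(r2)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  v <- v2 / 2
  z <- (v - mu) / sqrt(sig2)
  p_asym <- 2 * stats::pnorm(-abs(z))
  do_exact <- (mode == "exact") || (mode == "auto" && n <= 25)
  p_used <- if (do_exact) p_exact else p_asym
  structure(list(method = "signed_rank", statistic = v2 / 2,
                 p_exact = if (do_exact || mode == "auto") p_exact
                 else NA_real_,
                 p_asymptotic = p_asym,
                 p = min(1, m_comparisons * p_used),
                 correction = if (m_comparisons > 1) "bonferroni" else "none",
                 n = n), class = "test_result")
}

#' Exact Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact two-sided p-value from the full distribution of the group-A rank
#' sum over all \code{choose(n1+n2, n1)} group assignments (dynamic
#' programming; identical to enumeration), with midranks for ties. Falls
#' back to the tie-corrected normal approximation when the assignment count
#' exceeds \code{max_enumeration}.
#'
#' @param a,b numeric group samples.
#' @param mode \code{"exact"}, \code{"asymptotic"} or \code{"auto"}.
#' @param max_enumeration assignment-count limit for the exact path
#'   (default 1e6).
#' @return \code{test_result} with \code{statistic} (rank sum W of group a),
#'   \code{p_exact}, \code{p_asymptotic}, \code{p}, \code{n} (c(n1, n2)).
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "asymptotic"),
                              max_enumeration = 1e6) {
  mode <- match.arg(mode)
  n1 <- length(a)
  n2 <- length(b)
  stopifnot(n1 >= 1, n2 >= 1)
  pooled <- c(a, b)
  r2 <- .int_ranks2(pooled)
  w2 <- sum(r2[seq_len(n1)])
  n <- n1 + n2
  do_exact <- mode == "exact" ||
    (mode == "auto" && choose(n, n1) <= max_enumeration)
  p_exact <- NA_real_
  if (do_exact) {
    # counts[j+1, s+1] = number of j-subsets of processed ranks with
    # doubled-rank sum s
    smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
    counts <- matrix(0, n1 + 1, smax + 1)
    counts[1, 1] <- 1
    for (ri in r2) {
      for (j in n1:1) {
        src <- counts[j, ]
        if (!any(src > 0)) next
        shifted <- c(rep(0, ri), src)[seq_len(smax + 1)]
        counts[j + 1, ] <- counts[j + 1, ] + shifted
      }
    }
    dist <- counts[n1 + 1, ]
    total <- sum(dist)
    vals <- seq_along(dist) - 1
    p_low <- sum(dist[vals <= w2]) / total
    p_high <- sum(dist[vals >= w2]) / total
    p_exact <- min(1, 2 * min(p_low, p_high))
  }
  # tie-corrected normal approximation
  w <- w2 / 2
  mu <- n1 * (n + 1) / 2
  ties <- table(r2)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (w - mu) / sqrt(sig2)
  p_asym <- 2 * stats::pnorm(-abs(z))
  p_used <- if (do_exact) p_exact else p_asym
  structure(list(method = "rank_sum", statistic = w,
                 p_exact = p_exact, p_asymptotic = p_asym, p = p_used,
                 correction = "none", n = c(n1, n2)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s test: statistic %.4g, exact p %s, asymptotic p %.4g%s\n",
              x$method, x$statistic,
              ifelse(is.na(x$p_exact), "-", sprintf("%.4g", x$p_exact)),
              x$p_asymptotic,
              if (identical(x$correction, "bonferroni")) {
                sprintf(" (bonferroni p %.4g)", x$p)
              } else ""))
  invisible(x)
}
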