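# Packaged reference cohort measurements (7 T calf 23Na study: 10 healthy
# subjects with three repeated sessions, 5 Addison's-disease patients with
# one session; and the relaxometry subgroup of 4 healthy subjects).

#' Reference TSC repeatability measurements
#'
#' Long-format tissue sodium concentrations (mmol/L) per subject, group
#' (healthy / Addison's disease), session (M1-M3) and muscle (GM, TA, S),
#' after B0/B1 and partial-volume corrections. 10 healthy subjects with
#' three sessions each and 5 patients with one session: 105 records.
#'
#' @return data.frame with columns \code{subject}, \code{group},
#'   \code{session}, \code{muscle}, \code{tsc}, \code{tsc_sd}.
#' @export
reference_tsc_table <- function() {
  path <- system.file("extdata", "cohort_tsc_sessions.csv",
                      package = "natriq")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference muscle relaxation-time measurements
#'
#' Per-subject, per-muscle 23Na relaxation times of the healthy relaxometry
#' subgroup (4 subjects x 3 muscles): T1, long and short T2* components
#' (ms) with their component fractions (percent).
#'
#' @return data.frame with columns \code{subject}, \code{muscle},
#'   \code{t1}, \code{t1_sd}, \code{t2l}, \code{t2l_sd}, \code{fl},
#'   \code{t2s}, \code{t2s_sd}, \code{fs}.
#' @export
reference_relaxation_table <- function() {
  path <- system.file("extdata", "cohort_relaxation_times.csv",
                      package = "natriq")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Per-muscle subject x session matrix from the TSC table
#'
#' @param table a TSC table as from \code{\link{reference_tsc_table}}.
#' @param muscle muscle name.
#' @param group subject group (default "healthy").
#' @return numeric matrix, subjects x sessions.
#' @export
tsc_session_matrix <- function(table, muscle, group = "healthy") {
  sub <- table[table$muscle == muscle & table$group == group, ]
  mat <- tapply(sub$tsc, list(sub$subject, sub$session), mean)
  mat[order(as.numeric(rownames(mat))), , drop = FALSE]
}

#' Per-subject session-mean TSC values by muscle
#'
#' The per-subject value entering the Friedman and group-comparison tests:
#' mean over available sessions for each muscle.
#'
#' @inheritParams tsc_session_matrix
#' @return numeric matrix, subjects x muscles (GM, TA, S).
#' @export
tsc_subject_means <- function(table, group = "healthy") {
  sub <- table[table$group == group, ]
  mat <- tapply(sub$tsc, list(sub$subject, sub$muscle), mean)
  mat <- mat[order(as.numeric(rownames(mat))), c("GM", "TA", "S"),
             drop = FALSE]
  mat
}
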