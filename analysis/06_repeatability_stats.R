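#!/usr/bin/env Rscript
# Repeatability and group statistics on the reference cohort TSC table:
# two-way ICC per muscle, Bland-Altman session agreement, Friedman test
# across muscles, pairwise signed-rank tests and healthy-vs-Addison
# rank-sum comparisons. Also renders the Bland-Altman panel as a PDF.

suppressPackageStartupMessages(library(natriq))

dir.create("results", showWarnings = FALSE)
tab <- reference_tsc_table()
rep <- analyze_repeatability(tab)

cat("Cohort means (healthy, n = 10; mean over sessions):\n")
print(round(rep$means$healthy, 2))
cat("Cohort means (Addison, n = 5):\n")
print(round(rep$means$addison, 2))

cat("\nICC (two-way, average measures, consistency):\n")
for (m in names(rep$icc)) print(rep$icc[[m]])
cat("Absolute-agreement counterpart (average measures):\n")
for (m in names(rep$icc_absolute)) print(rep$icc_absolute[[m]])

cat("\nFriedman test across muscles:\n")
print(rep$friedman)
cat("\nPairwise signed-rank tests (Bonferroni m = 3):\n")
for (p in names(rep$pairwise)) {
  cat(" ", p, ": "); print(rep$pairwise[[p]])
}
cat("\nHealthy vs Addison rank-sum tests:\n")
for (m in names(rep$group_comparison)) {
  cat(" ", m, ": "); print(rep$group_comparison[[m]])
}

icc_df <- do.call(rbind, lapply(names(rep$icc), function(m) {
  x <- rep$icc[[m]]
  data.frame(muscle = m, icc = x$value, ci_low = x$ci_low,
             ci_high = x$ci_high)
}))
write.csv(icc_df, "results/icc_summary.csv", row.names = FALSE)

pdf("results/bland_altman.pdf", width = 9, height = 9)
op <- par(mfrow = c(3, 3), mar = c(4, 4, 2, 1))
for (nm in names(rep$bland_altman)) {
  b <- rep$bland_altman[[nm]]
  plot(b$averages, b$differences, pch = 19,
       xlab = "mean of sessions (mmol/L)",
       ylab = "difference (mmol/L)", main = nm,
       ylim = range(c(b$differences, b$loa_low, b$loa_high)))
  abline(h = c(b$mean_diff, b$loa_low, b$loa_high),
         lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
}
par(op)
dev.off()
cat("\nwrote results/icc_summary.csv and results/bland_altman.pdf\n")
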