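#!/usr/bin/env Rscript
# Paired statistical comparison of the four plan setups per metric:
# Shapiro-Wilk normality gate on pairwise differences (descriptive),
# Friedman omnibus, then pairwise Wilcoxon signed-rank with Bonferroni
# correction where the omnibus is significant.
# Requires results/cohort_evaluation.csv (analysis/01).

suppressMessages(library(breastplanr))
dir.create("results", showWarnings = FALSE)

ev <- read_cohort_csv("results/cohort_evaluation.csv")
reports <- breastplanr:::cohort_statistics(ev, alpha = 0.05)

for (m in names(reports)) {
  r <- reports[[m]]
  cat(sprintf("\n== %s ==\n", m))
  norm_frac <- mean(r$shapiro$shapiro_p > 0.05, na.rm = TRUE)
  cat(sprintf("pairwise differences looking normal (Shapiro p > 0.05): %d of 6\n",
              round(6 * norm_frac)))
  print(r)
}

tab <- breastplanr:::stats_report_table(reports)
write.csv(tab, "results/statistics.csv", row.names = FALSE)
cat("\nwrote results/statistics.csv\n")
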