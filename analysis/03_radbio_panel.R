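#!/usr/bin/env Rscript
# Radiobiological panel: EUD-based TCP per plan plus the six linear
# excess-risk estimates (acute coronary events, cardiac mortality,
# secondary lung-cancer mortality; each with/without risk factor).
# Requires results/cohort_evaluation.csv (analysis/01).

suppressMessages(library(breastplanr))
dir.create("results", showWarnings = FALSE)

ev <- read_cohort_csv("results/cohort_evaluation.csv")
s <- summarize_cohort(ev)
tabs <- render_summary(s)
write.csv(tabs$risk, "results/table_risk_panel.csv", row.names = FALSE)

cat("TCP and excess-risk panel, median (Q1-Q3) per setup:\n")
print(tabs$risk, row.names = FALSE)

low_tcp <- vapply(unique(ev$setup), function(st)
  round(100 * mean(ev$tcp[ev$setup == st] < 0.95)), numeric(1))
cat("\npatients with TCP below 95% [%]:\n")
print(low_tcp)
cat(sprintf("\nmean DLS-DLP TCP: %.1f%% (cold-spot subpopulation drags the mean\nwell below the median %.1f%%)\n",
            100 * mean(ev$tcp[ev$setup == "DLS_DLP"]),
            100 * median(ev$tcp[ev$setup == "DLS_DLP"])))
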