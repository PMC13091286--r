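#!/usr/bin/env Rscript
# Simulate the default synthetic cohort: 101 virtual left-breast patients,
# four plan setups each (CS-CP, DLS-DLP, CS-DLP, PS-DLP), DVH-level
# fidelity. Writes the per-patient evaluation table and a provenance echo
# of every generator assumption under results/.

suppressMessages(library(breastplanr))
dir.create("results", showWarnings = FALSE)

cfg <- run_config(cohort = cohort_config(n_patients = 101, seed = 20260930),
                  out_dir = "results")
co <- generate_cohort(cfg$cohort)
write_cohort_csv(co$evals, file.path(cfg$out_dir, "cohort_evaluation.csv"))
jsonlite::write_json(breastplanr:::serialize_config(cfg),
                     file.path(cfg$out_dir, "provenance.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

ev <- co$evals
cat(sprintf("simulated %d patients x %d setups (%d plan evaluations)\n",
            length(unique(ev$patient_id)), length(unique(ev$setup)),
            nrow(ev)))
cat(sprintf("defect subpopulation (clinically relevant DLS target error): %d patients\n",
            sum(ev$setup == "DLS_DLP" & ev$tcp < 0.95)))
cat("wrote results/cohort_evaluation.csv and results/provenance.json\n")
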