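#!/usr/bin/env Rscript
# Stage 2: evaluate every plan of the cohort.
#
# Reads the volume bundles written by stage 1, computes the full
# dose-volume / conformity / radiobiology metric panel and the clinical
# compliance check per plan, and writes results/panels.csv and
# results/compliance.csv.

suppressMessages(library(rtcohort))

cfg <- read_run_config("results/cohort_config.json")
dirs <- list.dirs("results/cohort", recursive = FALSE)
if (length(dirs) == 0) stop("run analysis/01_generate_cohort.R first")
plans <- lapply(dirs, read_volume_bundle)

ev <- evaluate_cohort(plans, cfg)
utils::write.csv(ev$panels, "results/panels.csv", row.names = FALSE)
utils::write.csv(ev$compliance, "results/compliance.csv", row.names = FALSE)

n_pass <- sum(tapply(ev$compliance$pass, ev$compliance$patient_id, all))
cat(sprintf("evaluated %d plans; %d/%d rules pass; all-rule pass in %d/%d patients\n",
            length(plans), sum(ev$compliance$pass), nrow(ev$compliance),
            n_pass, length(unique(ev$compliance$patient_id))))
cat("cohort mean lung V20 by modality (%):\n")
v20 <- ev$panels[ev$panels$structure == "lung" & ev$panels$metric == "V20", ]
print(round(tapply(v20$value, v20$modality, mean), 1))
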