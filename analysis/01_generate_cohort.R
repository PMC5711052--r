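#!/usr/bin/env Rscript
# Stage 1: generate the synthetic phantom cohort.
#
# Eight phantom patients, each with a CRT, an IMRT and a VMAT dose
# distribution at a 60 Gy prescription, written as NIfTI volume bundles
# under results/cohort/ for the downstream stages.

suppressMessages(library(rtcohort))

cfg <- run_config(n_patients = 8, seed = 1)
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write_run_config(cfg, file.path("results", "cohort_config.json"))

plans <- generate_cohort(n = cfg$n_patients, seed = cfg$seed,
                         prescription = cfg$prescription_gy,
                         shape = cfg$shape, spacing = cfg$spacing)

for (p in plans) {
  write_volume_bundle(p, file.path(out, sprintf("%s_%s", p$patient_id, p$modality)))
}

vols <- vapply(plans[seq(1, length(plans), by = 3)], function(p) {
  sum(p$structures$ptv$mask) * voxel_volume_cc(p$dose)
}, numeric(1))
cat(sprintf("wrote %d plans (%d patients x 3 modalities) to %s\n",
            length(plans), cfg$n_patients, out))
cat(sprintf("PTV volumes: %.1f-%.1f cm^3 (median %.1f)\n",
            min(vols), max(vols), stats::median(vols)))
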