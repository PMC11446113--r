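#!/usr/bin/env Rscript
# Stage 1: synthesize the phantom cohort.
# Writes per-case NIfTI volumes/masks, the clinical table and the ground
# truth under results/cohort/.

source("analysis/00_config.R")

coh <- generate_cohort(STUDY_SPEC, dir = COHORT_DIR)
write.csv(coh$clinical, file.path(COHORT_DIR, "clinical.csv"),
          row.names = FALSE)

cat(sprintf("cohort: %d cases, %.1f%% malignant\n",
            nrow(coh$clinical), 100 * mean(coh$labels)))
cat(sprintf("CT report agrees with pathology in %.1f%% of cases\n",
            100 * mean(ifelse(coh$labels == 1, "malignant", "benign") ==
                       coh$clinical$ct_report)))
tab <- table(truth = coh$labels, report = coh$clinical$ct_report)
print(tab)
ks <- vapply(coh$cases, function(cs) cs$truth$true_population_count, 0L)
cat("ground-truth population counts by class:\n")
print(table(label = coh$labels, k = ks))
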