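#!/usr/bin/env Rscript
# Stage 5: two-step feature selection on the development cohort only —
# ICC(2,1) >= 0.85 stability filter between the two raters, then Student's
# t-test (P < 0.001). Writes results/features/selection.csv.

source("analysis/00_config.R")

clinical <- read.csv(file.path(COHORT_DIR, "clinical.csv"))
tabA <- read.csv(file.path(FEATURES_DIR, "features_full_raterA.csv"),
                 check.names = FALSE)
tabB <- read.csv(file.path(FEATURES_DIR, "features_full_raterB.csv"),
                 check.names = FALSE)

split <- split_by_date(clinical, STUDY_CFG$dev_fraction)
dev <- clinical$case_id %in% split$development
sel <- select_features(tabA[dev, ], tabB[dev, ], clinical$label[dev],
                       STUDY_CFG$selection)
write.csv(sel$report, file.path(FEATURES_DIR, "selection.csv"),
          row.names = FALSE)

rep <- sel$report
cat(sprintf("development cohort: %d cases; features in: %d\n",
            sum(dev), nrow(rep)))
cat(sprintf("removed by ICC < %.2f: %d; removed by t-test: %d; kept: %d\n",
            STUDY_CFG$selection$icc_threshold,
            sum(rep$stage_of_removal == "stability"),
            sum(rep$stage_of_removal == "significance"),
            length(sel$kept)))
kept_ith <- sum(startsWith(sel$kept, "ITH__"))
cat(sprintf("kept ITH (diversity) features: %d\n", kept_ith))
by_roi <- table(sub("__.*", "", sel$kept))
print(by_roi)
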