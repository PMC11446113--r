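#!/usr/bin/env Rscript
# Stage 6: model fitting on the development cohort. Clinical-factor and
# CT-report logistic models, stacked ensemble on the selected radiomics+ITH
# features, combined ensemble with clinical factors, LASSO comparator and
# risk+CT fusion. Writes per-case risks to results/models/risks.csv.

source("analysis/00_config.R")

clinical <- read.csv(file.path(COHORT_DIR, "clinical.csv"))
tabA <- read.csv(file.path(FEATURES_DIR, "features_full_raterA.csv"),
                 check.names = FALSE)
sel <- read.csv(file.path(FEATURES_DIR, "selection.csv"))
kept <- sel$feature[sel$kept]

split <- split_by_date(clinical, STUDY_CFG$dev_fraction)
dev <- clinical$case_id %in% split$development

t0 <- Sys.time()
models <- suppressWarnings(
  fit_study_models(tabA, clinical, clinical$label, dev, kept,
                   seed = STUDY_SEED))
risks <- risk_table(models, tabA, clinical, dev)
write.csv(risks, file.path(MODELS_DIR, "risks.csv"), row.names = FALSE)
jsonlite::write_json(
  list(seed = STUDY_SEED, n_features = length(kept),
       base_learners = renorad:::base_learner_roster(),
       meta_learner = "logistic", cv_folds = 5),
  file.path(MODELS_DIR, "model_manifest.json"), auto_unbox = TRUE)

cat(sprintf("fitted %d models on %d development cases (%d features) in %.1f min\n",
            length(models), sum(dev), length(kept),
            as.numeric(Sys.time() - t0, units = "mins")))
te <- !dev
for (m in setdiff(names(risks), c("case_id", "cohort")))
  cat(sprintf("  test AUC %-14s %.3f\n", m,
              roc_auc(risks[[m]][te], clinical$label[te])))
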