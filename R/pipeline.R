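#' Study run configuration
#'
#' Bundles every tunable of the end-to-end replica: the phantom spec, the
#' discretization and selection settings, the development fraction, the
#' mask-perturbation magnitude for the stability rater and the global seed.
#' Validated before any compute; everything lands in the run manifest.
#'
#' @param phantom a [phantom_spec()].
#' @param disc a [disc_config()].
#' @param selection a [selection_config()].
#' @param dev_fraction development-cohort fraction in (0, 1).
#' @param perturb_mm boundary perturbation (mm) for the second rater.
#' @param n_segments subregion request per lesion.
#' @param seed global seed for modeling.
#' @return object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(),
                       disc = disc_config(),
                       selection = selection_config(),
                       dev_fraction = 0.66,
                       perturb_mm = 1.5,
                       n_segments = 100L,
                       seed = 1L) {
  stopifnot(inherits(phantom, "phantom_spec"))
  if (dev_fraction <= 0 || dev_fraction >= 1)
    stop("dev_fraction must lie in (0, 1)")
  if (perturb_mm < 0) stop("perturb_mm must be >= 0")
  structure(list(phantom = phantom, disc = disc, selection = selection,
                 dev_fraction = dev_fraction, perturb_mm = perturb_mm,
                 n_segments = as.integer(n_segments),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the end-to-end study replica
#'
#' Stages, in order: phantom cohort -> eight-ROI feature tables for two
#' segmentation raters -> intratumoral diversity vectors -> two-step feature
#' selection -> model fitting on the development cohort (clinical LR,
#' CT-report LR, radiomics+ITH stacked ensemble, combined ensemble, LASSO
#' comparator, risk+CT fusion) -> evaluation on the held-out test cohort.
#' Tabular artifacts are written under `out_dir` per stage, with a JSON
#' manifest; stages whose artifact already exists are reloaded when
#' `resume = TRUE`.
#'
#' @param config a [run_config()].
#' @param out_dir artifact directory.
#' @param resume reload stage outputs that already exist (default TRUE).
#' @param write_images also persist volumes/masks as NIfTI (default FALSE).
#' @return invisible list with the tables, models, risks and `eval_report`.
#' @export
run_study <- function(config, out_dir, resume = TRUE, write_images = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dirs <- file.path(out_dir, c("cohort", "features", "models", "eval"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = rapply(unclass(config), unclass,
                                   how = "replace"),
                   package_version = as.character(
                     utils::packageVersion("renorad")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  # stage: cohort -----------------------------------------------------------
  cohort <- generate_cohort(config$phantom,
                            dir = if (write_images)
                              file.path(out_dir, "cohort") else NULL)
  write.csv(cohort$clinical, file.path(out_dir, "cohort", "clinical.csv"),
            row.names = FALSE)
  message("stage cohort: ", nrow(cohort$clinical), " cases")

  # stage: features (two raters) + ITH --------------------------------------
  fa_path <- file.path(out_dir, "features", "features_raterA.csv")
  fb_path <- file.path(out_dir, "features", "features_raterB.csv")
  if (resume && file.exists(fa_path) && file.exists(fb_path)) {
    tabA <- read.csv(fa_path, check.names = FALSE)
    tabB <- read.csv(fb_path, check.names = FALSE)
    message("stage features: reloaded")
  } else {
    masksB <- lapply(seq_along(cohort$cases), function(i)
      perturb_mask(cohort$cases[[i]]$mask, magnitude_mm = config$perturb_mm,
                   seed = case_seed(config$phantom$seed, i, 9L)))
    tabA <- cohort_feature_table(cohort$cases, config$disc)
    tabB <- cohort_feature_table(cohort$cases, config$disc, masks = masksB)
    divA <- div_for_masks(cohort$cases, NULL, config)
    divB <- div_for_masks(cohort$cases, masksB, config)
    tabA <- bind_diversity(tabA, divA)
    tabB <- bind_diversity(tabB, divB)
    write.csv(tabA, fa_path, row.names = FALSE)
    write.csv(tabB, fb_path, row.names = FALSE)
    message("stage features: ", ncol(tabA) - 1, " columns per rater")
  }

  # stage: selection ---------------------------------------------------------
  split <- split_by_date(cohort$clinical, config$dev_fraction)
  dev <- cohort$clinical$case_id %in% split$development
  sel <- select_features(tabA[dev, ], tabB[dev, ],
                         cohort$labels[dev], config$selection)
  write.csv(sel$report, file.path(out_dir, "features", "selection.csv"),
            row.names = FALSE)
  message("stage select: ", length(sel$kept), " features kept")

  # stage: models ------------------------------------------------------------
  models <- fit_study_models(tabA, cohort$clinical, cohort$labels, dev,
                             sel$kept, config$seed)
  risks <- risk_table(models, tabA, cohort$clinical, dev)
  write.csv(risks, file.path(out_dir, "models", "risks.csv"),
            row.names = FALSE)
  message("stage models: ", length(models), " models fitted")

  # stage: eval --------------------------------------------------------------
  test <- !dev
  report <- stratified_report(risks$combined[test], cohort$labels[test],
                              cohort$clinical[test, ])
  report$pairwise <- list(
    combined_vs_clinical = delong_test(risks$combined[test],
                                       risks$clinical[test],
                                       cohort$labels[test]),
    combined_vs_ct = delong_test(risks$combined[test], risks$ct_report[test],
                                 cohort$labels[test]))
  report$model_aucs <- vapply(
    setdiff(names(risks), c("case_id", "cohort")),
    function(m) roc_auc(risks[[m]][test], cohort$labels[test]), 0)
  write_eval_report(report, file.path(out_dir, "eval", "eval_report.json"))
  message("stage eval: combined test AUC ",
          sprintf("%.3f", report$overall$auc))
  invisible(list(cohort = cohort, features = list(A = tabA, B = tabB),
                 selection = sel, split = split, models = models,
                 risks = risks, report = report))
}

# Diversity vectors for each case (optionally with replacement masks).
div_for_masks <- function(cases, masks, config) {
  lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    msk <- if (is.null(masks)) cs$mask else masks[[i]]
    sm <- segment_subregions(cs$volume, msk, config$n_segments,
                             seed = case_seed(config$phantom$seed, i, 5L))
    diversity_vector(cs$volume, sm, config$disc,
                     seed = case_seed(config$phantom$seed, i, 6L))
  })
}

clinical_feature_table <- function(clinical) {
  data.frame(case_id = clinical$case_id,
             age = clinical$age,
             male = as.integer(clinical$gender == "male"),
             lesion_size_cm = clinical$lesion_size_cm,
             stringsAsFactors = FALSE)
}

ct_feature_table <- function(clinical) {
  data.frame(case_id = clinical$case_id,
             ct_malignant = as.integer(clinical$ct_report == "malignant"),
             ct_equivocal = as.integer(clinical$ct_report == "equivocal"),
             stringsAsFactors = FALSE)
}

#' Fit the study's model roster
#'
#' @param table full feature table (radiomics + `ITH__` columns).
#' @param clinical clinical table aligned with it.
#' @param labels 0/1 vector.
#' @param dev logical development-cohort indicator.
#' @param kept selected feature names for the radiomics+ITH block.
#' @param seed integer seed.
#' @return named list of fitted models (`clinical`, `ct_report`,
#'   `radiomics_ith`, `combined`, `lasso`, `fusion`).
#' @export
fit_study_models <- function(table, clinical, labels, dev, kept, seed = 1L) {
  rad_tab <- table[, c("case_id", kept), drop = FALSE]
  clin_tab <- clinical_feature_table(clinical)
  ct_tab <- ct_feature_table(clinical)
  comb_tab <- cbind(rad_tab, clin_tab[, -1, drop = FALSE])
  y <- labels[dev]
  models <- list(
    clinical = fit_model(model_spec("logistic", "clinical", seed = seed),
                         clin_tab[dev, ], y),
    ct_report = fit_model(model_spec("logistic", "ct_report", seed = seed),
                          ct_tab[dev, ], y),
    radiomics_ith = fit_model(
      model_spec("stacked_ensemble", "radiomics_ith", seed = seed),
      rad_tab[dev, ], y),
    combined = fit_model(
      model_spec("stacked_ensemble", "combined", seed = seed),
      comb_tab[dev, ], y),
    lasso = fit_model(model_spec("lasso", "radiomics_ith", seed = seed),
                      if (length(kept) >= 2) rad_tab[dev, ] else
                        comb_tab[dev, ], y))
  risk_comb <- predict_risk(models$combined, comb_tab)
  models$fusion <- fuse_with_ct_report(risk_comb, clinical$ct_report,
                                       labels, dev)
  models
}

#' Risk table for every fitted model
#'
#' Test-cohort risks come from models trained on development cases only.
#'
#' @param models a [fit_study_models()] result.
#' @param table feature table for all cases.
#' @param clinical clinical table.
#' @param dev logical development indicator.
#' @return data.frame: case_id, cohort, one risk column per model.
#' @export
risk_table <- function(models, table, clinical, dev) {
  clin_tab <- clinical_feature_table(clinical)
  ct_tab <- ct_feature_table(clinical)
  kept <- models$radiomics_ith$feature_names
  comb_tab <- cbind(table[, c("case_id", kept), drop = FALSE],
                    clin_tab[, -1, drop = FALSE])
  risk_comb <- predict_risk(models$combined, comb_tab)
  data.frame(
    case_id = clinical$case_id,
    cohort = ifelse(dev, "development", "test"),
    clinical = predict_risk(models$clinical, clin_tab),
    ct_report = predict_risk(models$ct_report, ct_tab),
    radiomics_ith = predict_risk(models$radiomics_ith,
                                 table[, c("case_id", kept), drop = FALSE]),
    combined = risk_comb,
    lasso = predict_risk(models$lasso,
                         if (identical(models$lasso$feature_names, kept))
                           table[, c("case_id", kept), drop = FALSE]
                         else comb_tab),
    fusion = predict_fusion(models$fusion, risk_comb, clinical$ct_report),
    stringsAsFactors = FALSE)
}
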