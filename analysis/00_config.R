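# Shared configuration for the analysis scripts. Sourced by every numbered
# driver; all paths are relative to the repository root.

library(renorad)

RESULTS <- "results"
COHORT_DIR <- file.path(RESULTS, "cohort")
FEATURES_DIR <- file.path(RESULTS, "features")
MODELS_DIR <- file.path(RESULTS, "models")
EVAL_DIR <- file.path(RESULTS, "eval")

STUDY_SEED <- 2024L

# Cohort of 48 phantom lesions: enough for a 66/34 temporal split with both
# classes in each cohort while keeping the feature-extraction stage quick.
STUDY_SPEC <- phantom_spec(
  n_cases = 48L,
  seed = STUDY_SEED,
  spacing_mm = c(1, 1, 1),
  lesion_radius_range_mm = c(8, 13),
  n_populations = list(benign = 1:2, malignant = 2:4),
  population_separation = 120,
  noise_sd = 6,
  rim_contrast = 25,
  prevalence = 0.778
)

STUDY_CFG <- run_config(
  phantom = STUDY_SPEC,
  disc = disc_config(),
  selection = selection_config(),
  dev_fraction = 0.66,
  perturb_mm = 1.5,
  n_segments = 100L,
  seed = STUDY_SEED
)

for (d in c(COHORT_DIR, FEATURES_DIR, MODELS_DIR, EVAL_DIR))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)

# Reload persisted cohort volumes/masks written by 01_simulate.R, so each
# stage runs from the previous stage's artifacts only.
load_cases <- function() {
  clinical <- read.csv(file.path(COHORT_DIR, "clinical.csv"))
  cases <- lapply(clinical$case_id, function(id) {
    vol <- read_volume(file.path(COHORT_DIR, paste0(id, "_img.nii.gz")))
    mimg <- read_volume(file.path(COHORT_DIR, paste0(id, "_msk.nii.gz")))
    mask <- mimg > 0.5
    attr(mask, "spacing") <- voxel_spacing(mimg)
    list(volume = vol, mask = mask, truth = list(case_id = id))
  })
  list(cases = cases, clinical = clinical, labels = clinical$label)
}

rater_b_masks <- function(cases) {
  lapply(seq_along(cases), function(i)
    perturb_mask(cases[[i]]$mask, magnitude_mm = STUDY_CFG$perturb_mm,
                 seed = renorad:::case_seed(STUDY_SEED, i, 9L)))
}
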