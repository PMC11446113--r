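#' Phantom cohort specification
#'
#' Defines a synthetic cohort of 3-D lesion phantoms with known ground-truth
#' heterogeneity and clinical covariate structure. Each lesion is a digital
#' sphere whose interior is tiled by `n_populations` spatially contiguous
#' intensity populations (Voronoi regions around interior seeds), plus
#' Gaussian noise; malignant lesions additionally carry a peritumoral rim
#' offset in the 0-3 mm shell. Clinical covariates are drawn conditional on
#' the class label so the configured univariate log-odds hold in expectation.
#'
#' @param n_cases number of lesions (>= 1).
#' @param seed global integer seed; per-case streams are derived from it, so
#'   any case is reproducible in isolation.
#' @param spacing_mm voxel spacing in mm (3-vector, all > 0).
#' @param lesion_radius_range_mm `c(lo, hi)` lesion radius range in mm.
#' @param n_populations integer vector of candidate ground-truth population
#'   counts per case (each in 1..6), or a list with elements `benign` and
#'   `malignant` giving class-specific candidate sets.
#' @param population_separation mean HU gap between adjacent population means.
#' @param noise_sd additive Gaussian noise SD in HU (>= 0).
#' @param rim_contrast HU offset added to the 0-3 mm peritumoral shell of
#'   malignant lesions (benign lesions get no rim offset).
#' @param prevalence malignant prevalence.
#' @param clinical_effects list of covariate effect settings:
#'   `gender_lor` (log-odds of male for malignant vs benign),
#'   `male_base` (male fraction among benign), `age_base` (mean, sd in
#'   years for benign), `age_shift` (years added for malignant),
#'   `size_meanlog`/`size_sdlog` (log-normal size in cm, benign),
#'   `size_shift_log` (log-size shift for malignant), `ct_probs` with
#'   per-class probabilities over CT report categories
#'   (malignant, equivocal, benign).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_cases = 60L,
                         seed = 1L,
                         spacing_mm = c(1, 1, 1),
                         lesion_radius_range_mm = c(8, 14),
                         n_populations = list(benign = 1:2, malignant = 2:4),
                         population_separation = 120,
                         noise_sd = 6,
                         rim_contrast = 25,
                         prevalence = 0.778,
                         clinical_effects = list()) {
  eff <- utils::modifyList(list(
    gender_lor = 1.6,
    male_base = 0.316,
    age_base = c(50, 13),
    age_shift = 6,
    size_meanlog = log(3.9),
    size_sdlog = 0.40,
    size_shift_log = log(3.5 / 3.9),
    ct_probs = list(malignant = c(malignant = 0.821, equivocal = 0.151,
                                  benign = 0.028),
                    benign = c(malignant = 0.256, equivocal = 0.118,
                               benign = 0.627))
  ), clinical_effects)
  if (!is.list(n_populations))
    n_populations <- list(benign = n_populations, malignant = n_populations)
  spec <- structure(list(
    n_cases = as.integer(n_cases), seed = as.integer(seed),
    spacing_mm = as.numeric(spacing_mm),
    lesion_radius_range_mm = as.numeric(lesion_radius_range_mm),
    n_populations = lapply(n_populations, as.integer),
    population_separation = population_separation,
    noise_sd = noise_sd, rim_contrast = rim_contrast,
    prevalence = prevalence, clinical_effects = eff,
    margin_mm = 7), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (n_cases < 1L) stop("n_cases must be >= 1")
    if (any(spacing_mm <= 0)) stop("spacing components must be positive")
    if (lesion_radius_range_mm[1] > lesion_radius_range_mm[2])
      stop("lesion radius range must satisfy lo <= hi")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (!all(unlist(n_populations) %in% 1:6))
      stop("n_populations values must lie in 1..6")
    if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  })
  invisible(spec)
}

# Counter-based per-case seed stream: each (global seed, case, substream)
# triple maps to an independent 31-bit seed.
case_seed <- function(seed, case_index, sub = 0L) {
  s <- (as.double(seed) %% 2147483647) * 69621 + case_index * 100003 +
    sub * 7919 + 12345
  as.integer(s %% 2147483647)
}

ct_levels <- c("malignant", "equivocal", "benign")

# Per-case ground truth (label, covariates, geometry, population layout
# parameters). Deterministic in (spec, case_index).
case_truth <- function(spec, case_index) {
  stopifnot(case_index >= 1, case_index <= spec$n_cases)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(case_seed(spec$seed, case_index, 0L))
  eff <- spec$clinical_effects
  label <- rbinom(1, 1, spec$prevalence)
  p_male <- plogis(qlogis(eff$male_base) + eff$gender_lor * label)
  gender <- if (runif(1) < p_male) "male" else "female"
  age <- round(rnorm(1, eff$age_base[1] + eff$age_shift * label,
                     eff$age_base[2]))
  age <- min(max(age, 18), 90)
  size <- rlnorm(1, eff$size_meanlog + eff$size_shift_log * label,
                 eff$size_sdlog)
  size <- round(min(max(size, 0.9), 19.3), 1)
  laterality <- if (runif(1) < 0.47) "left" else "right"
  probs <- if (label == 1) eff$ct_probs$malignant else eff$ct_probs$benign
  ct_report <- sample(ct_levels, 1, prob = probs)
  radius <- runif(1, spec$lesion_radius_range_mm[1],
                  spec$lesion_radius_range_mm[2])
  cand <- if (label == 1) spec$n_populations$malignant else
    spec$n_populations$benign
  k <- if (length(cand) == 1) cand else sample(cand, 1)
  base_mean <- 80
  means <- base_mean + (seq_len(k) - 1) * spec$population_separation
  list(case_id = sprintf("case_%04d", case_index), label = label,
       gender = gender, age = age, lesion_size_cm = size,
       laterality = laterality, ct_report = ct_report,
       radius_mm = radius, true_population_count = k,
       population_means = means)
}

#' Generate one phantom lesion
#'
#' Builds the arterial-phase-like volume and lesion mask for one case. The
#' mask is a digital sphere (single 6-connected component) with at least a
#' 5 mm guaranteed shell inside the volume bounds. In-mask voxels are drawn
#' from the case's ground-truth population mixture (contiguous Voronoi
#' regions) plus Gaussian noise; malignant cases get `rim_contrast` added in
#' the 0-3 mm peritumoral shell. Identical `(spec, case_index)` give
#' bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @param case_index case number in `1..n_cases`.
#' @return list with `volume` (array + spacing), `mask` (logical array) and
#'   `truth` (per-case ground truth list).
#' @export
generate_lesion <- function(spec, case_index) {
  truth <- case_truth(spec, case_index)
  sp <- spec$spacing_mm
  r <- truth$radius_mm
  half <- r + spec$margin_mm
  dims <- as.integer(ceiling(2 * half / sp)) + 1L
  centre <- (dims - 1) / 2 * sp
  if (any((dims - 1) * sp < 2 * (r + 5)))
    stop("lesion radius + 5 mm margin exceeds volume extent")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(case_seed(spec$seed, case_index, 1L))

  ax <- (seq_len(dims[1]) - 1) * sp[1] - centre[1]
  ay <- (seq_len(dims[2]) - 1) * sp[2] - centre[2]
  az <- (seq_len(dims[3]) - 1) * sp[3] - centre[3]
  d2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  mask <- d2 <= r^2
  n_in <- sum(mask)

  vol <- array(30, dims)
  k <- truth$true_population_count
  in_idx <- which(mask)
  if (k == 1) {
    pop <- rep(1L, n_in)
  } else {
    coords <- voxel_coords(in_idx, dims, sp)
    seeds <- coords[sample(n_in, k), , drop = FALSE]
    dmat <- sapply(seq_len(k), function(j)
      colSums((t(coords) - seeds[j, ])^2))
    pop <- max.col(-dmat)
    # guarantee every population is realised
    for (j in which(tabulate(pop, k) == 0)) pop[sample(n_in, 1)] <- j
  }
  vol[in_idx] <- truth$population_means[pop]
  # class-dependent peritumoral rim in the 0-3 mm shell
  shell <- !mask & d2 <= (r + 3)^2
  vol[shell] <- vol[shell] + spec$rim_contrast * truth$label
  if (spec$noise_sd > 0)
    vol <- vol + array(rnorm(length(vol), 0, spec$noise_sd), dims)
  truth$population_voxels <- tabulate(if (k == 1) rep(1L, n_in) else pop, k)
  list(volume = image_volume(vol, sp),
       mask = structure(mask, spacing = sp),
       truth = truth)
}

#' Generate a phantom cohort
#'
#' Runs [generate_lesion()] for every case and assembles the clinical table.
#' The CT-report category is the class label passed through the configured
#' per-class report probabilities; `surgery_date` is a deterministic index
#' used by [split_by_date()].
#'
#' @param spec a [phantom_spec()].
#' @param dir optional directory; when given, volumes and masks are written
#'   as NIfTI, the clinical table as CSV and the spec + ground truth as JSON.
#' @param clinical_only skip volume synthesis and return only the clinical
#'   table and labels (the per-case truth stream is identical either way).
#' @return list with `cases` (per-case volume/mask/truth; `NULL` when
#'   `clinical_only`), `clinical` (data.frame) and `labels` (integer vector).
#' @export
generate_cohort <- function(spec, dir = NULL, clinical_only = FALSE) {
  validate_phantom_spec(spec)
  if (clinical_only) {
    truths <- lapply(seq_len(spec$n_cases),
                     function(i) case_truth(spec, i))
    cases <- lapply(truths, function(t) list(truth = t))
  } else {
    cases <- lapply(seq_len(spec$n_cases),
                    function(i) generate_lesion(spec, i))
  }
  clinical <- do.call(rbind, lapply(cases, function(cs) {
    t <- cs$truth
    data.frame(case_id = t$case_id, age = t$age, gender = t$gender,
               laterality = t$laterality, lesion_size_cm = t$lesion_size_cm,
               ct_report = t$ct_report, label = t$label,
               stringsAsFactors = FALSE)
  }))
  clinical$surgery_date <- seq_len(nrow(clinical))
  if (!is.null(dir) && !clinical_only) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (cs in cases) {
      write_volume(cs$volume, file.path(dir, paste0(cs$truth$case_id, "_img.nii.gz")))
      write_volume(cs$mask * 1, file.path(dir, paste0(cs$truth$case_id, "_msk.nii.gz")))
    }
    write.csv(clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
    truths <- lapply(cases, function(cs) cs$truth)
    jsonlite::write_json(list(spec = unclass(spec), truth = truths),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cases = cases, clinical = clinical, labels = clinical$label)
}

#' Perturb a lesion mask within a boundary band
#'
#' Produces a plausible second segmentation ("rater B") by moving the mask
#' boundary with a smooth random field of amplitude at most `magnitude_mm`.
#' The symmetric difference with the input is confined to the band of
#' physical distance `magnitude_mm` around the original boundary;
#' `magnitude_mm = 0` returns the input unchanged.
#'
#' @param mask 3-D logical array.
#' @param spacing voxel spacing in mm.
#' @param magnitude_mm maximum boundary displacement in mm (>= 0).
#' @param seed integer seed.
#' @return perturbed logical mask.
#' @export
perturb_mask <- function(mask, spacing = voxel_spacing(mask), magnitude_mm,
                         seed = 1L) {
  stopifnot(magnitude_mm >= 0)
  if (magnitude_mm == 0) return(mask)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  d <- dim(mask)
  # signed distance to boundary: positive inside, negative outside
  din <- distance_to_mask(!mask, spacing)   # inside: distance to background
  dout <- distance_to_mask(mask, spacing)   # outside: distance to foreground
  sdist <- ifelse(mask, din, -dout)
  # smooth displacement field: coarse white noise, trilinearly upsampled
  coarse_sp <- pmax(spacing * 4, 4)
  cd <- pmax(2L, as.integer(ceiling((d - 1) * spacing / coarse_sp)) + 1L)
  g <- array(rnorm(prod(cd)), cd)
  attr(g, "spacing") <- (d - 1) * spacing / (cd - 1)
  f <- resample_volume(g, spacing, method = "linear")
  f <- f[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
  # unit-SD field scaled to half the band, hard-clipped to the band
  f <- f / sd(f) * magnitude_mm / 2
  f <- pmin(pmax(f, -magnitude_mm), magnitude_mm)
  out <- sdist > f
  if (!any(out)) stop("mask perturbation emptied the mask")
  attr(out, "spacing") <- spacing
  out
}
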