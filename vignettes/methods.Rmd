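---
title: "Radiomics and intratumoral heterogeneity for renal lesion classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics and intratumoral heterogeneity for renal lesion classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Benign renal tumors (predominantly angiomyolipoma) and renal cell carcinoma
can look alike on contrast-enhanced CT, and radiologists' reads leave a
substantial fraction of lesions equivocal or misclassified. `renorad`
implements a complete, testable replica of a radiomics pipeline for this
problem: quantitative features from eight intratumoral and peritumoral
regions, an explicit intratumoral-heterogeneity (ITH) statistic built from
subregion clustering, reproducibility- and significance-based feature
selection, a stacked ensemble classifier fused with clinical factors, and
the standard evaluation suite (DeLong AUC inference, decile calibration,
decision curves, sensitivity/specificity-anchored cutoffs, subgroup and
small-renal-lesion analyses).

Because no patient cohort ships with the package, a 3-D phantom generator
with known ground truth stands in for the CT data. Every stage is exercised
against that ground truth; what that does and does not demonstrate about
real data is discussed at the end.

## Regions of interest

The lesion mask defines the intratumoral region (ITR). Seven further masks
are derived with *physical-distance* morphology: `ITR-3mm` (3 mm shrink),
`ITR+3mm` and `ITR+5mm` (expansions), and four peritumoral shells obtained
as exact set differences (`PTR0~+3mm`, `PTR0~+5mm`, `PTR-3~+3mm`,
`PTR-3~+5mm`). Offsets are applied by thresholding an exact anisotropic
Euclidean distance transform rather than by repeated voxel dilation, so a
"3 mm" margin is 3 mm whether the grid is 1 mm isotropic or 0.7 x 0.7 x
2.5 mm. The nesting and difference identities are asserted voxel-exactly in
the tests. Erosion can empty the mask for sub-6-mm lesions; the policy is
to flag the case and mark that ROI's features missing rather than drop the
case (the source protocol does not state a policy; this one is lossless and
auditable). Peritumoral masks are not clipped to an organ mask — none is
defined for the phantom — but a clipping hook exists.

## The 93-feature set

Per (volume, mask) pair the package computes 18 first-order statistics on
the raw HU values plus five texture-matrix classes on discretized values:
GLCM (24), GLDM (14), GLRLM (16), GLSZM (16) and NGTDM (5), i.e. 93
features, named `<class>_<feature>`. Matrix definitions follow the IBSI
conventions: symmetric GLCM at voxel distance 1, run-length and
co-occurrence accumulated over all 13 unique 3-D directions and merged
before feature computation, 26-connected zones for GLSZM, dependence
threshold 0 for GLDM, 26-connected neighborhood means for NGTDM. Matrix
accumulation runs in compiled code; each accumulator is verified
element-wise against an independent brute-force enumeration on small
integer arrays.

Tunables, with defaults and rationale:

* **Discretization** — fixed bin width, 25 HU. The source protocol defers
  to IBSI, and fixed-bin-width is the IBSI recommendation for CT because it
  keeps bin edges stable in HU across lesions. Bins are anchored at the
  in-mask minimum, so texture features are invariant to global intensity
  shifts (asserted in tests).
* **Resampling** — to 1 mm isotropic before texture extraction (linear for
  the image, nearest for the mask); direction-merged 3-D matrices are
  otherwise biased on anisotropic grids. The phantom default grid is
  already isotropic, in which case this is the identity.
* **Minimum mask size** — 10 voxels; texture matrices are unstable below
  this, and the ITH stage uses the same floor for subregions.

Shape and filtered-image features are deliberately excluded: the full
1,781-per-ROI configuration of the source protocol is specified only in an
unavailable appendix, so the 93-feature class set is the normative core
here, and the extractor accepts a plug-in for anything beyond it.

## Intratumoral heterogeneity as ecological diversity

The ITH statistic treats a tumor as an ecosystem of intensity habitats:

1. **Subregions.** The ITR is partitioned into ~100 superpixels by SLIC
   (simple linear iterative clustering) restricted to the mask: local
   k-means on standardized intensity and physical coordinates, grid pitch
   `S = (V/100)^(1/3)`, compactness 0.05 (intensity-dominant, so subregions
   align with intensity habitats), 10 iterations; segments under 10 voxels
   are merged into their most intensity-similar neighbor.
2. **Per-segment features.** The same 93 features are computed on every
   retained segment, with the discretization reference (in-mask minimum)
   taken per segment.
3. **Per-feature mixture complexity.** For each feature, the distribution
   of its per-segment values is fitted with one-dimensional Gaussian
   mixtures for k = 1..5 (EM, 5 restarts, variance floor `1e-6 var`,
   sorted inputs so the result is invariant to segment relabeling) and the
   k minimizing `BIC = -2 logL + (3k-1) log n` is selected, ties toward
   smaller k. The 93 selected counts form the ecological diversity vector.

The phantom ties this to ground truth: lesions are built from k spatially
contiguous intensity populations (Voronoi cells around interior seeds), and
the tests require the mean-intensity diversity entry to recover the true k
in at least 80% of replicates when populations are separated by 30 noise
SDs, with recovery degrading monotonically as separation shrinks.

One subtlety is deliberate: on a perfectly homogeneous lesion, every
*intensity-driven* feature is constant across segments and its diversity is
exactly 1, but features that measure segment geometry (run lengths, zone
sizes, dependence counts, Energy) vary with segment size and shape even at
constant intensity, so their diversity can exceed 1. This is a property of
per-segment radiomics itself, not noise; the tests pin the exact split.

## Feature selection

Two filters, applied to development-cohort data only, in the stated order:

* **Stability.** Each case is re-segmented by a simulated second rater
  (smooth random boundary perturbation confined to a ±1.5 mm band) and the
  full table is re-extracted. Features with ICC(2,1) — two-way random
  effects, absolute agreement, single measurement — below 0.85 are
  excluded. ICC(2,1) is the conservative choice when only "inter- and
  intra-observer ICC" is stated.
* **Significance.** Two-sample pooled-variance (Student's) t-test per
  feature; keep P < 0.001. No multiple-testing correction, mirroring the
  source protocol; a Benjamini-Hochberg switch exists but defaults off.
  The null behavior of the filter (type-I error ≈ α over 1000 null
  features) is asserted in the tests.

Both filters report on every input feature regardless of the other's
outcome, so the selection report records the stage of removal per feature.

## Models

The development/test split is temporal: cases sorted by surgery date, the
earliest 66% forming the development cohort. Models:

* clinical-factor logistic regression (age, gender, lesion size);
* CT-report logistic regression (one-hot of malignant/equivocal/benign);
* a **stacked ensemble** on the selected radiomics + ITH features —
  ridge-penalized logistic, random forest, extremely randomized trees,
  gradient boosting and k-NN base learners produce out-of-fold predictions
  under stratified 5-fold CV, a logistic meta-learner with non-negative
  weights combines them (the classical stacking constraint: on small
  cohorts an unconstrained meta-fit can learn negative weights from noisy
  out-of-fold predictions and invert the risk ranking), and the bases are
  refitted on the full development set. An explicit roster replaces the
  original AutoML system, whose "best quality" preset is not a reproducible
  contract; the tests require the ensemble to be within 0.01 AUC of its
  best base learner;
* the **combined model**: the same ensemble with clinical factors appended;
* a LASSO comparator (penalty by 5-fold CV deviance, 1-SE rule);
* **fusion**: logistic regression of the label on the combined model's risk
  plus the one-hot CT report, a concrete reading of "fusing" risk with the
  radiologists' read.

Missing cells (empty-ROI cases) are median-imputed from the training set;
prediction aligns columns by name; no evaluation metric is ever computed on
cases seen in training (asserted).

## Evaluation

AUC is the tie-corrected Mann-Whitney statistic. Confidence intervals and
paired comparisons use the DeLong placement-value method (normal
approximation, two-sided), cross-checked in the tests against an
independent implementation and a bootstrap, with 95% CI coverage verified
by simulation. Calibration groups the test cohort into equal-count deciles
of predicted risk (ties kept together, so heavy ties collapse bins) and
reports the sum of squared residuals between observed proportion and mean
predicted risk. Decision curves use
`NB(pt) = TP/n - FP/n * pt/(1-pt)` on a 0.01..0.99 grid of threshold
probabilities, with treat-all and treat-none references; the algebraic
identities (perfect classifier NB = prevalence; treat-all NB = 0 at
pt = prevalence) are asserted exactly. Cutoffs anchored at 99%/95%
sensitivity and 95%/99% specificity are searched over observed risk values
(largest threshold meeting a sensitivity target, smallest meeting a
specificity target), matching how discrete cutoffs are reported in
practice. Subgroup analyses stratify by age at 50 years, gender, lesion
size at 4.0 cm and CT-report category, and the whole suite is replicated on
the small-renal-lesion (≤ 4.0 cm) subset; the three-level CT report enters
ROC analysis through its fitted logistic risk, since an ordinal
ROC convention is not otherwise pinned down.

## The phantom: what it does and does not emulate

Each case is a digital sphere (radius 8-14 mm by default) in a padded
HU-like volume: background 30 HU, lesion populations starting at 80 HU and
separated by a configurable gap (default 120 HU), Gaussian noise (default
6 HU), and a class-dependent peritumoral rim (+25 HU in the 0-3 mm shell of
malignant lesions) so peritumoral ROIs carry signal. Population counts
default to 1-2 for benign and 2-4 for malignant lesions, making
heterogeneity itself discriminative. Clinical covariates are drawn
conditional on the label to match the published cohort's associations:
malignant prevalence 77.8%, male log-odds +1.6 (31.6% male among benign),
age +6 years, slightly smaller size (log-normal around 3.9 vs 3.5 cm), and
a CT report equal to the label passed through the published per-class
report distribution. Intensity levels themselves are free parameters — the
source reports no lesion HU statistics — so phantom HU ranges are *not*
calibrated to any cohort.

The generator is a pure function of its spec: a single global seed expands
into counter-based per-case streams, so any case is reproducible in
isolation and full cohorts are bit-identical across runs.

What passing tests show: the geometry, the feature definitions, the
mixture-complexity statistic, the selection logic, the leakage discipline
and the evaluation algebra are correct, and the pipeline recovers planted
effects (population counts, covariate log-odds, class signal) at realistic
noise. What they do not show: performance on real CT — phantoms have no
organ anatomy, no partial-volume or beam-hardening artifacts, no
segmentation ambiguity beyond the simulated rater band — so the published
patient-cohort AUCs are out of reach by construction and are not asserted
anywhere.

## Numerical choices and degenerate inputs

* EDT: exact squared-distance lower-envelope transform with physical step
  sizes per axis.
* GMM: variance floor `1e-6 var(x)` prevents singular spikes; inputs sorted;
  k capped at the number of distinct values; all-equal input short-circuits
  to k = 1 with a relative tolerance of 1e-9 for "equal".
* Constant regions: defined fixed points (entropy 0, uniformity 1, GLCM
  correlation 1); isolated-voxel segments make the NGTDM neighborhood empty
  and return its fixed point rather than NaN.
* Empty erosions raise a typed condition carrying the lesion id; the
  feature table marks those cells missing, never silently zero.
* DeLong variance degenerating at AUC = 1 clips the CI to [0, 1] with a
  warning; single-class subgroups are flagged non-computable, never
  imputed.
* cv.glmnet folds are stratified by class so small imbalanced development
  cohorts cannot produce single-class folds.

## Problem sizes

The shipped analysis (`analysis/01..07`) runs 48 phantom cases end to end;
the test suite uses 9-18-case cohorts for pipeline smoke tests, 12-15
replicates per condition for recovery properties, 500 replicates for CI
coverage, and 1000-2000 draws for covariate-recovery checks. These sizes
give stable pass/fail behavior for the stated tolerances while keeping a
full run comfortably interactive.

## Known limitations

* Only the 93-feature class set is implemented; shape and filtered-image
  features are plug-in territory.
* SLIC here is mask-restricted local k-means without an explicit
  connectivity enforcement pass; scattered segments are possible at very
  low compactness (the NGTDM degenerate path covers the consequence).
* The CT-report fusion functional form (logistic on risk + one-hot) is one
  reasonable reading of "fused"; alternatives (stacking, discrete
  overrides) are not explored.
* Diversity entries of geometry-sensitive features reflect segment
  geometry as well as intensity habitats (see above); downstream selection
  treats them like any other feature and lets the data decide.
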