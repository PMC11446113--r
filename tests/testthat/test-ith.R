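test_that("subregion request defaults to 100 and tiles a uniform sphere", {
  expect_equal(eval(formals(segment_subregions)$n_segments), 100L)
  spec <- phantom_spec(n_cases = 1, seed = 51, n_populations = 1,
                       noise_sd = 0, lesion_radius_range_mm = c(10, 10))
  cs <- generate_lesion(spec, 1)
  sm <- segment_subregions(cs$volume, cs$mask, seed = 2)
  expect_equal(attr(sm, "n_requested"), 100L)
  sizes <- as.integer(table(sm[sm > 0]))
  # labels partition the ITR
  expect_equal(sum(sizes), sum(cs$mask))
  expect_true(all(sm[!cs$mask] == 0))
  # segments of a constant-intensity sphere have comparable volumes
  expect_lt(max(sizes) / min(sizes), 3)
  expect_true(all(sizes >= 10))
})

test_that("segments respect a high-contrast blob boundary", {
  spec <- phantom_spec(n_cases = 1, seed = 57, n_populations = 2,
                       population_separation = 200, noise_sd = 1,
                       lesion_radius_range_mm = c(10, 10))
  cs <- generate_lesion(spec, 1)
  sm <- segment_subregions(cs$volume, cs$mask, seed = 3)
  # ground-truth population of each voxel from its noiseless mean
  truthpop <- round((cs$volume - 80) / 200)
  mixed <- 0
  for (l in unique(sm[sm > 0])) {
    pops <- sort(table(truthpop[sm == l]), decreasing = TRUE)
    if (length(pops) > 1 && pops[2] / sum(pops) > 0.2) mixed <- mixed + 1
  }
  # almost no retained segment straddles the blob boundary substantially
  expect_lte(mixed, 3)
})

test_that("segment request larger than the ITR is reduced with a warning", {
  spec <- phantom_spec(n_cases = 1, seed = 5, n_populations = 1,
                       noise_sd = 0, lesion_radius_range_mm = c(2.2, 2.2))
  cs <- generate_lesion(spec, 1)
  expect_warning(sm <- segment_subregions(cs$volume, cs$mask, 100, seed = 1),
                 "reducing")
  expect_lte(length(unique(sm[sm > 0])), sum(cs$mask))
})

test_that("BIC model selection recovers the component count", {
  expect_equal(gmm_bic_select(rep(3.3, 50)), 1L)
  expect_error(gmm_bic_select(c(1)), "at least 2")
  set.seed(8)
  x2 <- c(rnorm(50, 0, 1), rnorm(50, 100, 1))
  expect_equal(gmm_bic_select(x2, seed = 1), 2L)
  # direct BIC computation confirms the margin between k = 1 and k = 2
  ll1 <- sum(dnorm(x2, mean(x2), sqrt(mean((x2 - mean(x2))^2)), log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(100)
  fit2 <- function(x) { # two-component fit at the obvious split
    g <- x > 50
    sum(vapply(c(FALSE, TRUE), function(s) {
      xs <- x[g == s]
      sum(dnorm(xs, mean(xs), sd(xs), log = TRUE) + log(mean(g == s)))
    }, 0))
  }
  bic2 <- -2 * fit2(x2) + 5 * log(100)
  expect_lt(bic2, bic1)
  # six well-separated means: selection is capped at 5
  set.seed(9)
  x6 <- as.vector(vapply(0:5, function(j) rnorm(30, j * 50, 1),
                         numeric(30)))
  expect_equal(gmm_bic_select(x6, seed = 2), 5L)
})

test_that("BIC selection agrees with an independent mixture fit", {
  suppressMessages(library(mclust))
  set.seed(12)
  cases <- list(rnorm(80), c(rnorm(40, 0), rnorm(40, 30, 2)),
                c(rnorm(30, 0), rnorm(30, 25), rnorm(30, 60)))
  for (x in cases) {
    mc <- Mclust(x, G = 1:5, modelNames = "V", verbose = FALSE)
    expect_equal(gmm_bic_select(x, seed = 3), mc$G)
  }
})

test_that("diversity vector length, range, and ground-truth recovery", {
  cs <- cached_case()  # 3 well-separated populations
  sm <- segment_subregions(cs$volume, cs$mask, seed = 7)
  dv <- diversity_vector(cs$volume, sm, seed = 7)
  expect_length(dv, 93)
  expect_identical(names(dv), feature_names())
  expect_true(all(dv >= 1 & dv <= 5))
  expect_equal(unname(dv["firstorder_Mean"]), 3L)
  # permuting segment ids leaves the vector unchanged
  labs <- sort(unique(sm[sm > 0]))
  perm <- sample(labs)
  sm2 <- sm
  sm2[sm > 0] <- perm[match(sm[sm > 0], labs)]
  attributes(sm2) <- attributes(sm)
  dv2 <- diversity_vector(cs$volume, sm2, seed = 7)
  expect_identical(unclass(dv2), unclass(dv))
})

test_that("homogeneous lesions give unit diversity on intensity features", {
  spec <- phantom_spec(n_cases = 1, seed = 3, n_populations = 1,
                       noise_sd = 0, lesion_radius_range_mm = c(9, 9))
  cs <- generate_lesion(spec, 1)
  sm <- segment_subregions(cs$volume, cs$mask, seed = 3)
  dv <- diversity_vector(cs$volume, sm, seed = 3)
  # purely intensity-driven features are identical in every segment of a
  # constant lesion, so their diversity must be 1; run/zone/dependence
  # geometry features legitimately vary with segment size and shape
  intensity_driven <- c(
    setdiff(grep("^firstorder_", names(dv), value = TRUE),
            c("firstorder_Energy", "firstorder_TotalEnergy")),
    grep("^glcm_", names(dv), value = TRUE),
    grep("^ngtdm_", names(dv), value = TRUE),
    "glrlm_GrayLevelVariance", "glrlm_GrayLevelNonUniformityNormalized",
    "glrlm_LowGrayLevelRunEmphasis", "glrlm_HighGrayLevelRunEmphasis",
    "glszm_GrayLevelVariance", "glszm_GrayLevelNonUniformityNormalized",
    "glszm_LowGrayLevelZoneEmphasis", "glszm_HighGrayLevelZoneEmphasis",
    "gldm_GrayLevelVariance", "gldm_LowGrayLevelEmphasis",
    "gldm_HighGrayLevelEmphasis")
  expect_true(all(dv[intensity_driven] == 1L))
  # degenerate map with a single segment: flagged all-ones vector
  one_seg <- array(0L, dim(cs$mask))
  one_seg[cs$mask] <- 1L
  attr(one_seg, "spacing") <- c(1, 1, 1)
  expect_warning(dv1 <- diversity_vector(cs$volume, one_seg, seed = 1),
                 "fewer than 2")
  expect_true(all(dv1 == 1L))
})

test_that("heterogeneity recovery holds and degrades with separation", {
  # modal recovery of k over phantom replicates, on the per-segment mean
  recover <- function(k, separation, n_rep, seed0) {
    hits <- vapply(seq_len(n_rep), function(r) {
      spec <- phantom_spec(n_cases = 1, seed = seed0 + r,
                           n_populations = k,
                           population_separation = separation,
                           noise_sd = 5, lesion_radius_range_mm = c(9, 11))
      cs <- generate_lesion(spec, 1)
      sm <- segment_subregions(cs$volume, cs$mask, seed = seed0 + r)
      vals <- vapply(sort(unique(sm[sm > 0])),
                     function(l) mean(cs$volume[sm == l]), 0)
      gmm_bic_select(vals, 5, seed = seed0 + r)
    }, 0L)
    mean(hits == k)
  }
  # separation 150 = 30 x noise SD: at least 80% of cases recover true k
  for (k in 1:3)
    expect_gte(recover(k, 150, 15, 600 + 40 * k), 0.8)
  # recovery is non-increasing as separation shrinks (3-point grid, k = 2)
  rates <- vapply(c(150, 30, 6), function(s) recover(2, s, 12, 900), 0)
  expect_true(all(diff(rates) <= 0.1))
  expect_gt(rates[1], rates[3])
})
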