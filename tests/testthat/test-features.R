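test_that("fixed-bin-width discretization follows the floor formula", {
  vol <- array(0, c(4, 1, 1))
  vol[, 1, 1] <- c(0, 24.9, 25, 50)
  msk <- array(TRUE, c(4, 1, 1))
  b <- discretize(vol, msk, disc_config(bin_width = 25))
  expect_equal(as.integer(b), c(1L, 1L, 2L, 3L))
  # shift invariance: formula is anchored at the in-mask minimum
  expect_equal(discretize(vol + 1000, msk, disc_config(bin_width = 25)), b)
  # constant region: everything in bin 1, also under fixed bin count
  cvol <- array(7, c(3, 3, 3))
  cmsk <- array(TRUE, c(3, 3, 3))
  expect_true(all(discretize(cvol, cmsk, disc_config()) == 1L))
  expect_true(all(discretize(cvol, cmsk,
                             disc_config("fixed_bin_count")) == 1L))
})

test_that("the full feature vector has 93 stable named entries", {
  cs <- cached_case()
  f <- extract_features(cs$volume, cs$mask)
  expect_length(f, 93)
  expect_true(all(is.finite(f)))
  expect_identical(names(f), feature_names())
  counts <- table(sub("_.*", "", names(f)))
  expect_equal(as.integer(counts[c("firstorder", "glcm", "gldm", "glrlm",
                                   "glszm", "ngtdm")]),
               c(18L, 24L, 14L, 16L, 16L, 5L))
  # determinism
  expect_identical(f, extract_features(cs$volume, cs$mask))
})

test_that("constant regions sit at the analytic fixed points", {
  vol <- array(50, c(5, 5, 3))
  msk <- array(TRUE, c(5, 5, 3))
  f <- extract_features(vol, msk)
  expect_equal(unname(f["firstorder_Entropy"]), 0)
  expect_equal(unname(f["firstorder_Variance"]), 0)
  expect_equal(unname(f["firstorder_Uniformity"]), 1)
  expect_equal(unname(f["glcm_Contrast"]), 0)
  expect_equal(unname(f["glcm_JointEntropy"]), 0)
  expect_equal(unname(f["glcm_JointEnergy"]), 1)
  expect_equal(unname(f["glcm_Correlation"]), 1)
  expect_equal(unname(f["glcm_MaximumProbability"]), 1)
  expect_equal(unname(f["glrlm_GrayLevelVariance"]), 0)
  expect_equal(unname(f["glszm_GrayLevelVariance"]), 0)
  expect_equal(unname(f["ngtdm_Contrast"]), 0)
})

test_that("compiled texture matrices equal brute-force enumeration", {
  set.seed(99)
  for (rep in 1:4) {
    d <- c(sample(3:6, 1), sample(3:6, 1), sample(2:3, 1))
    bins <- array(sample(0:4, prod(d), replace = TRUE,
                         prob = c(0.2, rep(0.2, 4))), d)
    if (!any(bins > 0)) bins[1] <- 1L
    ng <- max(bins)
    expect_equal(renorad:::glcm_counts_cpp(bins, d, ng)[1:ng, 1:ng],
                 oracle_glcm(bins), ignore_attr = TRUE)
    glr <- renorad:::glrlm_counts_cpp(bins, d, ng)
    orc <- oracle_glrlm(bins)
    expect_equal(glr[, seq_len(ncol(orc))], orc, ignore_attr = TRUE)
    expect_true(all(glr[, -seq_len(ncol(orc)), drop = FALSE] == 0) ||
                ncol(glr) == ncol(orc))
    zc <- renorad:::glszm_zones_cpp(bins, d)
    zo <- oracle_glszm(bins)
    expect_equal(zc[order(zc[, 1], zc[, 2]), , drop = FALSE],
                 zo[order(zo[, 1], zo[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
    expect_equal(renorad:::gldm_counts_cpp(bins, d, ng, 0L),
                 oracle_gldm(bins), ignore_attr = TRUE)
    expect_equal(renorad:::ngtdm_stats_cpp(bins, d, ng),
                 oracle_ngtdm(bins), ignore_attr = TRUE)
  }
})

test_that("worked GLCM example matches pair accumulation by hand", {
  # 4 x 4 x 1 toy with two gray levels laid out in stripes
  bins <- array(rep(c(1L, 2L), 8), c(4, 4, 1))
  P <- renorad:::glcm_counts_cpp(bins, dim(bins), 2L)
  expect_equal(P, oracle_glcm(bins), ignore_attr = TRUE)
  Pn <- P / sum(P)
  f <- renorad:::glcm_features(P, c(1, 2))
  # contrast: sum of p * (i-j)^2 over the normalized matrix
  expect_equal(unname(f["Contrast"]),
               sum(Pn * outer(1:2, 1:2, function(a, b) (a - b)^2)))
  expect_equal(unname(f["JointEnergy"]), sum(Pn^2))
})

test_that("features are invariant to rotation, shift, and scale as claimed", {
  cs <- cached_case()
  f <- extract_features(cs$volume, cs$mask)
  # 90-degree in-plane rotation on an isotropic grid
  rot <- function(a) aperm(a[dim(a)[1]:1, , , drop = FALSE], c(2, 1, 3))
  vr <- rot(cs$volume); attr(vr, "spacing") <- c(1, 1, 1)
  mr <- rot(cs$mask); attr(mr, "spacing") <- c(1, 1, 1)
  fr <- extract_features(vr, mr)
  expect_equal(fr, f, tolerance = 1e-9)
  # global intensity shift: all discretized texture features unchanged
  fs <- extract_features(cs$volume + 500, cs$mask)
  tex <- grep("^(glcm|gldm|glrlm|glszm|ngtdm)_", names(f), value = TRUE)
  expect_equal(fs[tex], f[tex], tolerance = 1e-12)
  expect_equal(unname(fs["firstorder_Mean"] - f["firstorder_Mean"]), 500)
  # scale equivariance of the mean
  f2 <- extract_features(cs$volume * 2, cs$mask)
  expect_equal(unname(f2["firstorder_Mean"]), 2 * unname(f["firstorder_Mean"]))
})

test_that("per-ROI extraction yields 744 columns with missing ROIs marked", {
  cs <- cached_case()
  rs <- derive_rois(cs$mask)
  row <- extract_all_rois(cs$volume, rs)
  expect_length(row, 8 * 93)
  expect_true(all(is.finite(row)))
  expect_identical(row, extract_all_rois(cs$volume, rs))
  # an empty ITR-3mm marks exactly that ROI's columns missing
  tiny_spec <- phantom_spec(n_cases = 1, seed = 9,
                            lesion_radius_range_mm = c(2.5, 2.5))
  tiny <- generate_lesion(tiny_spec, 1)
  rs2 <- derive_rois(tiny$mask, on_empty = "flag")
  row2 <- extract_all_rois(tiny$volume, rs2)
  expect_equal(attr(row2, "missing_rois"), "ITR-3mm")
  na_cols <- names(row2)[is.na(row2)]
  expect_true(all(startsWith(na_cols, "ITR-3mm__")))
  expect_equal(length(na_cols), 93)
  # a sub-minimum mask raises the feature error
  small <- array(FALSE, c(6, 6, 6)); small[3, 3, 3] <- TRUE
  expect_error(extract_features(array(1, c(6, 6, 6)), small),
               class = "renorad_feature_error")
})
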