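#' Discretization settings for texture analysis
#'
#' @param mode `"fixed_bin_width"` (default, recommended for CT) or
#'   `"fixed_bin_count"`.
#' @param bin_width bin width in HU (default 25).
#' @param bin_count number of bins for `fixed_bin_count` (default 32).
#' @param resample_spacing_mm spacing to resample to before texture
#'   extraction (default 1 mm isotropic); `NULL` disables resampling.
#' @return object of class `disc_config`.
#' @export
disc_config <- function(mode = c("fixed_bin_width", "fixed_bin_count"),
                        bin_width = 25, bin_count = 32L,
                        resample_spacing_mm = c(1, 1, 1)) {
  mode <- match.arg(mode)
  stopifnot(bin_width > 0, bin_count >= 2)
  structure(list(mode = mode, bin_width = bin_width,
                 bin_count = as.integer(bin_count),
                 resample_spacing_mm = resample_spacing_mm),
            class = "disc_config")
}

#' Discretize in-mask intensities into integer bins
#'
#' Fixed-bin-width: bin = floor((x - min) / w) + 1 with the minimum taken
#' over the mask, so bin 1 always contains the in-mask minimum and binning
#' is invariant to global intensity shifts. Fixed-bin-count: the in-mask
#' range is split into `bin_count` equal bins (a constant region yields a
#' single bin).
#'
#' @param volume 3-D numeric array.
#' @param mask 3-D logical array (non-empty).
#' @param cfg a [disc_config()].
#' @return integer array, 0 outside the mask, bins `1..Ng` inside.
#' @export
discretize <- function(volume, mask, cfg = disc_config()) {
  stopifnot(any(mask))
  x <- volume[mask]
  if (cfg$mode == "fixed_bin_width") {
    b <- floor((x - min(x)) / cfg$bin_width) + 1
  } else {
    rg <- range(x)
    if (rg[1] == rg[2]) b <- rep(1, length(x))
    else b <- pmin(floor((x - rg[1]) / ((rg[2] - rg[1]) / cfg$bin_count)) + 1,
                   cfg$bin_count)
  }
  out <- array(0L, dim(volume))
  out[mask] <- as.integer(b)
  out
}

#' Names of the 93-feature radiomic set
#'
#' Eighteen first-order features plus the five texture-matrix classes
#' (GLCM 24, GLDM 14, GLRLM 16, GLSZM 16, NGTDM 5), named
#' `<class>_<feature>`.
#'
#' @param classes subset of
#'   `c("firstorder", "glcm", "gldm", "glrlm", "glszm", "ngtdm")`.
#' @return character vector of feature names (length 93 with all classes).
#' @export
feature_names <- function(classes = c("firstorder", "glcm", "gldm",
                                      "glrlm", "glszm", "ngtdm")) {
  all <- list(
    firstorder = c("Energy", "TotalEnergy", "Entropy", "Minimum",
                   "P10", "P90", "Maximum", "Mean", "Median",
                   "InterquartileRange", "Range", "MeanAbsoluteDeviation",
                   "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                   "Skewness", "Kurtosis", "Variance", "Uniformity"),
    glcm = c("Autocorrelation", "ClusterProminence", "ClusterShade",
             "ClusterTendency", "Contrast", "Correlation",
             "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
             "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
             "JointAverage", "JointEnergy", "JointEntropy", "MCC",
             "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"),
    gldm = c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
             "GrayLevelNonUniformity", "DependenceNonUniformity",
             "DependenceNonUniformityNormalized", "GrayLevelVariance",
             "DependenceVariance", "DependenceEntropy",
             "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
             "SmallDependenceLowGrayLevelEmphasis",
             "SmallDependenceHighGrayLevelEmphasis",
             "LargeDependenceLowGrayLevelEmphasis",
             "LargeDependenceHighGrayLevelEmphasis"),
    glrlm = c("ShortRunEmphasis", "LongRunEmphasis",
              "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
              "RunPercentage", "GrayLevelVariance", "RunVariance",
              "RunEntropy", "LowGrayLevelRunEmphasis",
              "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
              "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
              "LongRunHighGrayLevelEmphasis"),
    glszm = c("SmallAreaEmphasis", "LargeAreaEmphasis",
              "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
              "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
              "ZoneEntropy", "LowGrayLevelZoneEmphasis",
              "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
              "SmallAreaHighGrayLevelEmphasis",
              "LargeAreaLowGrayLevelEmphasis",
              "LargeAreaHighGrayLevelEmphasis"),
    ngtdm = c("Coarseness", "Contrast", "Busyness", "Complexity",
              "Strength"))
  classes <- match.arg(classes, names(all), several.ok = TRUE)
  unlist(lapply(classes, function(cl) paste0(cl, "_", all[[cl]])),
         use.names = FALSE)
}

log2p <- function(p) ifelse(p > 0, log2(p), 0)

fo_features <- function(x, bins, voxel_volume) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  p <- tabulate(bins) / n
  p <- p[p > 0]
  q <- quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  rob <- x[x >= q[1] & x <= q[5]]
  c(Energy = sum(x^2),
    TotalEnergy = voxel_volume * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x), P10 = q[1], P90 = q[5], Maximum = max(x),
    Mean = m, Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - m)),
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((x - m)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

glcm_features <- function(counts, v) {
  ng <- length(v)
  if (sum(counts) == 0) counts <- diag(1, ng)
  P <- counts / sum(counts)
  px <- rowSums(P)
  mu <- sum(px * v)
  sig2 <- sum(px * (v - mu)^2)
  V <- matrix(v, ng, ng)
  dv <- abs(V - t(V))
  sv <- V + t(V)
  HX <- -sum(log2p(px) * px)
  HXY <- -sum(log2p(P) * P)
  pxpy <- outer(px, px)
  HXY1 <- -sum(P * log2p(pxpy))
  HXY2 <- -sum(pxpy * log2p(pxpy))
  # difference / sum marginals
  dlev <- sort(unique(as.vector(dv)))
  pd <- vapply(dlev, function(k) sum(P[dv == k]), 0)
  slev <- sort(unique(as.vector(sv)))
  ps <- vapply(slev, function(k) sum(P[sv == k]), 0)
  da <- sum(dlev * pd)
  mcc <- if (ng == 1) 1 else {
    Q <- matrix(0, ng, ng)
    for (i in seq_len(ng)) for (j in seq_len(ng)) {
      den <- px[i] * px
      term <- ifelse(den > 0, P[i, ] * P[j, ] / den, 0)
      Q[i, j] <- sum(term)
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  }
  c(Autocorrelation = sum(P * V * t(V)),
    ClusterProminence = sum(P * (sv - 2 * mu)^4),
    ClusterShade = sum(P * (sv - 2 * mu)^3),
    ClusterTendency = sum(P * (sv - 2 * mu)^2),
    Contrast = sum(P * dv^2),
    Correlation = if (sig2 > 0) (sum(P * V * t(V)) - mu^2) / sig2 else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd * log2p(pd)),
    DifferenceVariance = sum(pd * (dlev - da)^2),
    Id = sum(P / (1 + dv)),
    Idm = sum(P / (1 + dv^2)),
    Idmn = sum(P / (1 + dv^2 / ng^2)),
    Idn = sum(P / (1 + dv / ng)),
    Imc1 = if (max(HX, HX) > 0) (HXY - HXY1) / HX else 0,
    Imc2 = sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0)),
    InverseVariance = sum((P / pmax(dv^2, 1))[dv > 0]),
    JointAverage = mu,
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(slev * ps),
    SumEntropy = -sum(ps * log2p(ps)),
    SumSquares = sig2)
}

# Shared machinery for the three gray-level x size-like matrices
# (run length, zone size, dependence): emphasis sums over counts N(i, s)
# with gray values v_i and size values s_j.
glxm_features <- function(N, v, s, nvox, denom_extra = 1) {
  Ns <- sum(N)
  p <- N / Ns
  rg <- rowSums(N)
  rs <- colSums(N)
  S <- matrix(s, nrow(N), ncol(N), byrow = TRUE)
  V2 <- matrix(v^2, nrow(N), ncol(N))
  mu_v <- sum(p * matrix(v, nrow(N), ncol(N)))
  mu_s <- sum(p * S)
  list(
    small = sum(N / S^2) / Ns,
    large = sum(N * S^2) / Ns,
    gln = sum(rg^2) / Ns,
    glnn = sum(rg^2) / Ns^2,
    sn = sum(rs^2) / Ns,
    snn = sum(rs^2) / Ns^2,
    pct = Ns / (nvox * denom_extra),
    glv = sum(p * (matrix(v, nrow(N), ncol(N)) - mu_v)^2),
    sv = sum(p * (S - mu_s)^2),
    entropy = -sum(p * log2p(p)),
    lgl = sum(N / V2) / Ns,
    hgl = sum(N * V2) / Ns,
    small_lgl = sum(N / (S^2 * V2)) / Ns,
    small_hgl = sum(N * V2 / S^2) / Ns,
    large_lgl = sum(N * S^2 / V2) / Ns,
    large_hgl = sum(N * S^2 * V2) / Ns,
    n_total = Ns)
}

glrlm_features <- function(counts, v, nvox) {
  g <- glxm_features(counts, v, seq_len(ncol(counts)), nvox,
                     denom_extra = 13)
  c(ShortRunEmphasis = g$small, LongRunEmphasis = g$large,
    GrayLevelNonUniformity = g$gln,
    GrayLevelNonUniformityNormalized = g$glnn,
    RunLengthNonUniformity = g$sn, RunLengthNonUniformityNormalized = g$snn,
    RunPercentage = g$pct, GrayLevelVariance = g$glv, RunVariance = g$sv,
    RunEntropy = g$entropy, LowGrayLevelRunEmphasis = g$lgl,
    HighGrayLevelRunEmphasis = g$hgl,
    ShortRunLowGrayLevelEmphasis = g$small_lgl,
    ShortRunHighGrayLevelEmphasis = g$small_hgl,
    LongRunLowGrayLevelEmphasis = g$large_lgl,
    LongRunHighGrayLevelEmphasis = g$large_hgl)
}

glszm_features <- function(zones, v_map, nvox) {
  # zones: 2-column matrix (compacted level, size)
  sizes <- sort(unique(zones[, 2]))
  ng <- length(v_map)
  N <- matrix(0, ng, length(sizes))
  for (r in seq_len(nrow(zones)))
    N[zones[r, 1], match(zones[r, 2], sizes)] <-
      N[zones[r, 1], match(zones[r, 2], sizes)] + 1
  g <- glxm_features(N, v_map, sizes, nvox)
  c(SmallAreaEmphasis = g$small, LargeAreaEmphasis = g$large,
    GrayLevelNonUniformity = g$gln,
    GrayLevelNonUniformityNormalized = g$glnn,
    SizeZoneNonUniformity = g$sn, SizeZoneNonUniformityNormalized = g$snn,
    ZonePercentage = g$n_total / nvox, GrayLevelVariance = g$glv,
    ZoneVariance = g$sv, ZoneEntropy = g$entropy,
    LowGrayLevelZoneEmphasis = g$lgl, HighGrayLevelZoneEmphasis = g$hgl,
    SmallAreaLowGrayLevelEmphasis = g$small_lgl,
    SmallAreaHighGrayLevelEmphasis = g$small_hgl,
    LargeAreaLowGrayLevelEmphasis = g$large_lgl,
    LargeAreaHighGrayLevelEmphasis = g$large_hgl)
}

gldm_features <- function(counts, v, nvox) {
  keep <- which(colSums(counts) > 0)
  g <- glxm_features(counts[, keep, drop = FALSE], v, keep, nvox)
  c(SmallDependenceEmphasis = g$small, LargeDependenceEmphasis = g$large,
    GrayLevelNonUniformity = g$gln, DependenceNonUniformity = g$sn,
    DependenceNonUniformityNormalized = g$snn, GrayLevelVariance = g$glv,
    DependenceVariance = g$sv, DependenceEntropy = g$entropy,
    LowGrayLevelEmphasis = g$lgl, HighGrayLevelEmphasis = g$hgl,
    SmallDependenceLowGrayLevelEmphasis = g$small_lgl,
    SmallDependenceHighGrayLevelEmphasis = g$small_hgl,
    LargeDependenceLowGrayLevelEmphasis = g$large_lgl,
    LargeDependenceHighGrayLevelEmphasis = g$large_hgl)
}

ngtdm_features <- function(stats, v) {
  n_i <- stats[, 1]
  s_i <- stats[, 2]
  N <- sum(n_i)
  if (N == 0) # every voxel isolated: no neighbourhood exists
    return(c(Coarseness = 1e6, Contrast = 0, Busyness = 0,
             Complexity = 0, Strength = 0))
  p <- n_i / N
  act <- p > 0
  ngp <- sum(act)
  vi <- v[act]; pi <- p[act]; si <- s_i[act]
  dvij <- outer(vi, vi, `-`)
  coarse_den <- sum(pi * si)
  contrast <- if (ngp > 1)
    sum(outer(pi, pi) * dvij^2) / (ngp * (ngp - 1)) * sum(si) / N else 0
  busy_den <- sum(abs(outer(vi * pi, vi * pi, `-`)))
  psum <- outer(pi, pi, `+`)
  complexity <- sum(abs(dvij) * (outer(pi * si, pi * si, `+`)) / psum) / N
  strength <- if (sum(si) > 0) sum(psum * dvij^2) / sum(si) else 0
  c(Coarseness = if (coarse_den > 0) 1 / coarse_den else 1e6,
    Contrast = contrast,
    Busyness = if (busy_den > 0) coarse_den / busy_den else 0,
    Complexity = complexity,
    Strength = strength)
}

feature_error <- function(msg) {
  structure(class = c("renorad_feature_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Extract the radiomic feature vector from a volume/mask pair
#'
#' Computes the 93-feature set (with all six classes enabled): first-order
#' statistics on the raw in-mask intensities, and texture features on
#' intensities discretized per `cfg`. Texture matrices are accumulated over
#' all 13 unique 3-D directions and merged before features are computed;
#' GLCM is symmetric at distance 1 voxel, GLDM uses dependence threshold 0,
#' NGTDM a 26-connected neighborhood. When the grid is anisotropic the pair
#' is first resampled to `cfg$resample_spacing_mm` (linear image / nearest
#' mask).
#'
#' @param volume 3-D numeric array.
#' @param mask 3-D logical array.
#' @param cfg a [disc_config()].
#' @param classes feature classes to compute (default all six; 93 values).
#' @param min_voxels minimum mask size (default 10); smaller masks raise a
#'   feature-error condition.
#' @param spacing voxel spacing in mm.
#' @return named numeric vector in the stable [feature_names()] order.
#' @export
extract_features <- function(volume, mask, cfg = disc_config(),
                             classes = c("firstorder", "glcm", "gldm",
                                         "glrlm", "glszm", "ngtdm"),
                             min_voxels = 10,
                             spacing = voxel_spacing(volume)) {
  if (sum(mask) < min_voxels)
    stop(feature_error(sprintf(
      "mask has %d voxels; minimum is %d", sum(mask), min_voxels)))
  if (!is.null(cfg$resample_spacing_mm) &&
      !isTRUE(all.equal(as.numeric(spacing),
                        as.numeric(cfg$resample_spacing_mm)))) {
    volume <- resample_volume(volume, cfg$resample_spacing_mm, spacing,
                              "linear")
    mask <- resample_volume(mask * 1, cfg$resample_spacing_mm, spacing,
                            "nearest") > 0.5
    spacing <- cfg$resample_spacing_mm
    if (sum(mask) < min_voxels)
      stop(feature_error("mask too small after resampling"))
  }
  bins_full <- discretize(volume, mask, cfg)
  # compact gray levels to those present; keep original bin values for the
  # intensity-weighted features
  lev <- sort(unique(bins_full[mask]))
  comp <- array(0L, dim(bins_full))
  comp[mask] <- match(bins_full[mask], lev)
  ng <- length(lev)
  v <- as.numeric(lev)
  nvox <- sum(mask)
  d <- dim(volume)
  out <- numeric(0)
  if ("firstorder" %in% classes)
    out <- c(out, prefix("firstorder",
                         fo_features(volume[mask], bins_full[mask],
                                     prod(spacing))))
  if ("glcm" %in% classes)
    out <- c(out, prefix("glcm",
                         glcm_features(glcm_counts_cpp(comp, d, ng), v)))
  if ("gldm" %in% classes)
    out <- c(out, prefix("gldm",
                         gldm_features(gldm_counts_cpp(comp, d, ng, 0L), v,
                                       nvox)))
  if ("glrlm" %in% classes)
    out <- c(out, prefix("glrlm",
                         glrlm_features(glrlm_counts_cpp(comp, d, ng), v,
                                        nvox)))
  if ("glszm" %in% classes)
    out <- c(out, prefix("glszm",
                         glszm_features(glszm_zones_cpp(comp, d), v, nvox)))
  if ("ngtdm" %in% classes)
    out <- c(out, prefix("ngtdm",
                         ngtdm_features(ngtdm_stats_cpp(comp, d, ng), v)))
  out[feature_names(intersect(c("firstorder", "glcm", "gldm", "glrlm",
                                "glszm", "ngtdm"), classes))]
}

prefix <- function(cl, x) setNames(x, paste0(cl, "_", names(x)))

#' Extract features from all eight ROIs of a case
#'
#' @param volume 3-D numeric array.
#' @param roiset a [derive_rois()] result.
#' @param cfg a [disc_config()].
#' @param classes feature classes (default all six).
#' @param min_voxels minimum ROI size; smaller or empty ROIs yield `NA`
#'   cells, explicitly marked missing rather than zero.
#' @return named numeric vector with `<ROI>__<feature>` entries
#'   (8 x 93 = 744 with all classes); attribute `missing_rois` lists ROIs
#'   whose cells are `NA`.
#' @export
extract_all_rois <- function(volume, roiset, cfg = disc_config(),
                             classes = c("firstorder", "glcm", "gldm",
                                         "glrlm", "glszm", "ngtdm"),
                             min_voxels = 10) {
  stopifnot(inherits(roiset, "roi_set"), length(roiset) == 8)
  fnames <- feature_names(classes)
  missing <- character()
  row <- unlist(lapply(names(roiset), function(rn) {
    vals <- tryCatch(
      extract_features(volume, roiset[[rn]], cfg, classes, min_voxels,
                       spacing = attr(roiset, "spacing")),
      renorad_feature_error = function(e) {
        missing <<- c(missing, rn)
        setNames(rep(NA_real_, length(fnames)), fnames)
      })
    setNames(vals, paste0(rn, "__", names(vals)))
  }))
  structure(row, missing_rois = missing)
}

#' Build a feature table over a cohort
#'
#' @param cases list of cases, each with `volume` and `mask` (e.g. from
#'   [generate_cohort()]); masks may be replaced via `masks`.
#' @param cfg a [disc_config()].
#' @param masks optional list of masks overriding each case's own (used for
#'   the perturbed-rater stability stream).
#' @param classes feature classes.
#' @return data.frame with `case_id` then `<ROI>__<feature>` columns.
#' @export
cohort_feature_table <- function(cases, cfg = disc_config(), masks = NULL,
                                 classes = c("firstorder", "glcm", "gldm",
                                             "glrlm", "glszm", "ngtdm")) {
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    msk <- if (is.null(masks)) cs$mask else masks[[i]]
    rs <- derive_rois(msk, voxel_spacing(msk), cs$truth$case_id,
                      on_empty = "flag")
    extract_all_rois(cs$volume, rs, cfg, classes)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  if (anyDuplicated(names(tab))) stop("duplicate feature columns")
  cbind(data.frame(case_id = vapply(cases, function(cs) cs$truth$case_id, ""),
                   stringsAsFactors = FALSE), tab)
}
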