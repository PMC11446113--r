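#' Feature-selection settings
#'
#' @param icc_threshold stability threshold (default 0.85): features with
#'   ICC below it are excluded.
#' @param alpha significance level for the two-sample Student's t-test
#'   (default 0.001).
#' @param adjust optional multiple-testing adjustment passed to
#'   [stats::p.adjust()]; default `"none"` (no correction).
#' @return object of class `selection_config`.
#' @export
selection_config <- function(icc_threshold = 0.85, alpha = 0.001,
                             adjust = "none") {
  stopifnot(icc_threshold > 0, icc_threshold < 1, alpha > 0, alpha < 1)
  structure(list(icc_threshold = icc_threshold, alpha = alpha,
                 adjust = adjust, icc_form = "ICC(2,1)"),
            class = "selection_config")
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' between two raters' per-case feature values, computed from the ANOVA
#' mean squares (Shrout & Fleiss):
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with `k = 2`.
#'
#' @param x1,x2 numeric vectors (rater A / rater B), equal length >= 3.
#' @return ICC in (-1, 1], or `NA` (flagged) when the total variance is 0.
#' @export
icc <- function(x1, x2) {
  stopifnot(length(x1) == length(x2), length(x1) >= 3)
  if (!all(is.finite(x1)) || !all(is.finite(x2))) return(NA_real_)
  n <- length(x1)
  k <- 2
  Y <- cbind(x1, x2)
  gm <- mean(Y)
  if (all(Y == Y[1])) return(NA_real_)
  row_m <- rowMeans(Y)
  col_m <- colMeans(Y)
  msr <- k * sum((row_m - gm)^2) / (n - 1)
  msc <- n * sum((col_m - gm)^2) / (k - 1)
  mse <- sum((Y - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + gm)^2) /
    ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (den <= 0) return(NA_real_)
  (msr - mse) / den
}

feature_columns <- function(table) {
  setdiff(names(table), c("case_id", "label", "surgery_date"))
}

#' Stability filter: keep features reproducible across segmentations
#'
#' Computes ICC(2,1) per feature between the primary feature table and one
#' built from perturbed masks, and keeps features with
#' `ICC >= icc_threshold`. Cases with missing cells in either table are
#' dropped for that feature.
#'
#' @param tableA,tableB feature tables with identical `case_id` and feature
#'   columns (B from a perturbed re-segmentation).
#' @param cfg a [selection_config()].
#' @return list with `kept` (character vector) and `report` (data.frame:
#'   feature, icc, kept).
#' @export
stability_filter <- function(tableA, tableB, cfg = selection_config()) {
  fa <- feature_columns(tableA)
  fb <- feature_columns(tableB)
  if (!identical(fa, fb) || !identical(tableA$case_id, tableB$case_id))
    stop("tables must share cases and feature columns")
  iccs <- vapply(fa, function(f) {
    ok <- is.finite(tableA[[f]]) & is.finite(tableB[[f]])
    if (sum(ok) < 3) return(NA_real_)
    icc(tableA[[f]][ok], tableB[[f]][ok])
  }, 0)
  kept <- !is.na(iccs) & iccs >= cfg$icc_threshold
  list(kept = fa[kept],
       report = data.frame(feature = fa, icc = unname(iccs),
                           kept = unname(kept), row.names = NULL))
}

#' Significance filter: two-sample Student's t-test per feature
#'
#' Pooled-variance (Student's) t-test of each feature between classes;
#' features with `P < alpha` are kept. Features with zero pooled variance
#' are skipped with a warning.
#'
#' @param table feature table.
#' @param labels 0/1 vector aligned with the table rows (both classes with
#'   >= 2 cases).
#' @param cfg a [selection_config()].
#' @return list with `kept` and `report` (feature, t, p, kept).
#' @export
significance_filter <- function(table, labels, cfg = selection_config()) {
  stopifnot(sum(labels == 0) >= 2, sum(labels == 1) >= 2)
  feats <- feature_columns(table)
  res <- lapply(feats, function(f) {
    x <- table[[f]]
    ok <- is.finite(x)
    g0 <- x[ok & labels == 0]
    g1 <- x[ok & labels == 1]
    if (length(g0) < 2 || length(g1) < 2)
      return(c(t = NA_real_, p = NA_real_))
    sp2 <- ((length(g0) - 1) * var(g0) + (length(g1) - 1) * var(g1)) /
      (length(g0) + length(g1) - 2)
    if (sp2 == 0) {
      warning("feature '", f, "' has zero pooled variance; skipped")
      return(c(t = NA_real_, p = NA_real_))
    }
    tt <- t.test(g1, g0, var.equal = TRUE)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  tp <- do.call(rbind, res)
  p_adj <- stats::p.adjust(tp[, "p"], method = cfg$adjust)
  kept <- !is.na(p_adj) & p_adj < cfg$alpha
  list(kept = feats[kept],
       report = data.frame(feature = feats, t = unname(tp[, "t"]),
                           p = unname(tp[, "p"]), kept = unname(kept),
                           row.names = NULL))
}

#' Two-step feature selection: stability then significance
#'
#' @param tableA,tableB feature tables (primary and perturbed-mask rater).
#' @param labels 0/1 vector.
#' @param cfg a [selection_config()].
#' @return list with `kept` and a combined `report` (feature, icc, t, p,
#'   kept, stage_of_removal).
#' @export
select_features <- function(tableA, tableB, labels,
                            cfg = selection_config()) {
  st <- stability_filter(tableA, tableB, cfg)
  sg <- significance_filter(tableA, labels, cfg)
  kept <- intersect(st$kept, sg$kept)
  stage <- ifelse(st$report$kept & sg$report$kept, "",
                  ifelse(!st$report$kept, "stability", "significance"))
  list(kept = kept,
       report = data.frame(feature = st$report$feature,
                           icc = st$report$icc, t = sg$report$t,
                           p = sg$report$p,
                           kept = st$report$kept & sg$report$kept,
                           stage_of_removal = stage, row.names = NULL))
}
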