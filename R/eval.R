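#' Area under the ROC curve
#'
#' Mann-Whitney U statistic scaled to `[0, 1]`; ties count one half.
#'
#' @param risks numeric scores (higher = more malignant).
#' @param labels 0/1 vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(risks, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(risks)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

# Placement values: V10 (per positive) and V01 (per negative).
delong_placements <- function(risks, labels) {
  x <- risks[labels == 1]
  y <- risks[labels == 0]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong AUC variance, confidence interval and paired test
#'
#' `delong_ci()` returns the AUC with its DeLong standard error and a
#' normal-approximation confidence interval (clipped to `[0, 1]`, with a
#' warning when the variance degenerates at AUC = 1).
#' `delong_test()` compares two paired risk vectors on the same cases using
#' the covariance of placement values; two-sided P.
#'
#' @param risks,risks_a,risks_b numeric scores.
#' @param labels 0/1 vector (same cases for the paired test).
#' @param conf confidence level (default 0.95).
#' @return `delong_ci`: list with `auc`, `se`, `ci` (length 2).
#'   `delong_test`: list with `auc_a`, `auc_b`, `delta`, `se`, `z`, `p`.
#' @export
delong_ci <- function(risks, labels, conf = 0.95) {
  pl <- delong_placements(risks, labels)
  m <- length(pl$v10)
  n <- length(pl$v01)
  v <- var(pl$v10) / m + var(pl$v01) / n
  if (!is.finite(v) || v <= 0) {
    warning("degenerate DeLong variance; CI clipped")
    v <- 0
  }
  z <- qnorm(1 - (1 - conf) / 2)
  ci <- pmin(pmax(pl$auc + c(-1, 1) * z * sqrt(v), 0), 1)
  list(auc = pl$auc, se = sqrt(v), ci = ci)
}

#' @rdname delong_ci
#' @export
delong_test <- function(risks_a, risks_b, labels) {
  stopifnot(length(risks_a) == length(risks_b))
  pa <- delong_placements(risks_a, labels)
  pb <- delong_placements(risks_b, labels)
  m <- length(pa$v10)
  n <- length(pa$v01)
  v <- var(pa$v10 - pb$v10) / m + var(pa$v01 - pb$v01) / n
  if (!is.finite(v)) v <- 0
  delta <- pa$auc - pb$auc
  if (v <= 0) {
    z <- if (delta == 0) 0 else sign(delta) * Inf
  } else z <- delta / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
       se = sqrt(max(v, 0)), z = z, p = 2 * pnorm(-abs(z)))
}

#' Decile calibration and sum of squared residuals
#'
#' Cases are grouped into `n_bins` equal-count bins of predicted risk with
#' tied risks kept in one bin (heavy ties can collapse bins, which is
#' reported). SSR is the sum over bins of
#' `(observed proportion - mean predicted)^2`.
#'
#' @param risks predicted probabilities.
#' @param labels 0/1 vector.
#' @param n_bins number of bins (default 10; `n >= n_bins` required).
#' @return list with `table` (bin, n, mean_predicted, observed) and `ssr`.
#' @export
calibration_ssr <- function(risks, labels, n_bins = 10L) {
  n <- length(risks)
  stopifnot(n >= n_bins)
  g <- floor((rank(risks, ties.method = "min") - 1) * n_bins / n) + 1
  bins <- sort(unique(g))
  if (length(bins) < n_bins)
    message("ties collapsed calibration bins to ", length(bins))
  tab <- do.call(rbind, lapply(bins, function(b) data.frame(
    bin = b, n = sum(g == b),
    mean_predicted = mean(risks[g == b]),
    observed = mean(labels[g == b]))))
  list(table = tab, ssr = sum((tab$observed - tab$mean_predicted)^2))
}

#' Decision-curve analysis
#'
#' Net benefit of treating cases with `risk >= pt`:
#' `NB(pt) = TP/n - (FP/n) * pt / (1 - pt)`, with the treat-all and
#' treat-none references.
#'
#' @param risks predicted probabilities.
#' @param labels 0/1 vector.
#' @param thresholds threshold probabilities in (0, 1)
#'   (default 0.01..0.99 step 0.01).
#' @return data.frame: threshold, net_benefit, treat_all, treat_none.
#' @export
decision_curve <- function(risks, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly within (0, 1)")
  n <- length(labels)
  pi_hat <- mean(labels == 1)
  nb <- vapply(thresholds, function(pt) {
    pred <- risks >= pt
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    tp / n - fp / n * pt / (1 - pt)
  }, 0)
  data.frame(threshold = thresholds, net_benefit = nb,
             treat_all = pi_hat - (1 - pi_hat) * thresholds / (1 - thresholds),
             treat_none = 0)
}

#' Sensitivity- and specificity-anchored risk cutoffs
#'
#' Candidate thresholds are the observed risk values (rule: positive when
#' `risk >= t`). Sensitivity-anchored cutoffs take the largest threshold
#' whose sensitivity still meets the target; specificity-anchored the
#' smallest threshold whose specificity meets it. Unattainable targets give
#' `NA`.
#'
#' @param risks predicted probabilities.
#' @param labels 0/1 vector (both classes present).
#' @param sens_targets sensitivity targets (default 0.99, 0.95).
#' @param spec_targets specificity targets (default 0.95, 0.99).
#' @return named list (`sens99`, `sens95`, `spec95`, `spec99` under the
#'   defaults) of thresholds.
#' @export
find_cutoffs <- function(risks, labels, sens_targets = c(0.99, 0.95),
                         spec_targets = c(0.95, 0.99)) {
  labels <- as.integer(labels)
  stopifnot(any(labels == 1), any(labels == 0))
  cand <- sort(unique(risks))
  sens <- vapply(cand, function(t) mean(risks[labels == 1] >= t), 0)
  spec <- vapply(cand, function(t) mean(risks[labels == 0] < t), 0)
  out <- list()
  for (s in sens_targets) {
    ok <- which(sens >= s)
    out[[sprintf("sens%d", round(100 * s))]] <-
      if (length(ok)) max(cand[ok]) else NA_real_
  }
  for (s in spec_targets) {
    ok <- which(spec >= s)
    out[[sprintf("spec%d", round(100 * s))]] <-
      if (length(ok)) min(cand[ok]) else NA_real_
  }
  out
}

#' Confusion matrix at a risk threshold
#'
#' @param risks predicted probabilities.
#' @param labels 0/1 vector.
#' @param threshold decision threshold (default 0.5, rule `risk >= t`).
#' @return 2x2 integer matrix (rows: truth, cols: prediction).
#' @export
confusion_matrix <- function(risks, labels, threshold = 0.5) {
  pred <- factor(as.integer(risks >= threshold), levels = c(0, 1))
  truth <- factor(as.integer(labels), levels = c(0, 1))
  m <- table(truth = truth, prediction = pred)
  matrix(as.integer(m), 2, 2,
         dimnames = list(truth = c("benign", "malignant"),
                         prediction = c("benign", "malignant")))
}

metric_suite <- function(risks, labels, n_bins = 10L) {
  ci <- delong_ci(risks, labels)
  list(auc = ci$auc, ci = ci$ci,
       calibration = if (length(risks) >= n_bins)
         calibration_ssr(risks, labels, n_bins) else NULL,
       cutoffs = find_cutoffs(risks, labels),
       confusion = confusion_matrix(risks, labels))
}

#' Evaluation report with subgroup and small-renal-lesion analyses
#'
#' Computes the full metric suite (DeLong AUC + CI, decile calibration SSR,
#' decision curve, anchored cutoffs, confusion matrix) on the whole cohort,
#' per clinical subgroup (age at 50 years, gender, lesion size at 4.0 cm,
#' CT-report category), and on the small-renal-lesion (<= 4.0 cm) subset.
#' Subgroups with a single class get a flagged, non-computable AUC.
#'
#' @param risks predicted probabilities (test cohort).
#' @param labels 0/1 vector.
#' @param clinical clinical data.frame aligned with the risks (columns
#'   `age`, `gender`, `lesion_size_cm`, `ct_report`).
#' @return object of class `eval_report`: list with `overall`,
#'   `decision_curve`, `subgroups` (AUC table) and `srl` (metric suite on
#'   the SRL subset, or flag).
#' @export
stratified_report <- function(risks, labels, clinical) {
  stopifnot(nrow(clinical) == length(risks))
  groups <- list(
    "age<=50"      = clinical$age <= 50,
    "age>50"       = clinical$age > 50,
    "male"         = clinical$gender == "male",
    "female"       = clinical$gender == "female",
    "size<=4cm"    = clinical$lesion_size_cm <= 4.0,
    "size>4cm"     = clinical$lesion_size_cm > 4.0,
    "ct_malignant" = clinical$ct_report == "malignant",
    "ct_equivocal" = clinical$ct_report == "equivocal",
    "ct_benign"    = clinical$ct_report == "benign")
  sub <- do.call(rbind, lapply(names(groups), function(g) {
    sel <- groups[[g]]
    if (sum(sel) < 2 || length(unique(labels[sel])) < 2)
      return(data.frame(subgroup = g, n = sum(sel), auc = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        flag = "non-computable"))
    ci <- delong_ci(risks[sel], labels[sel])
    data.frame(subgroup = g, n = sum(sel), auc = ci$auc,
               ci_lo = ci$ci[1], ci_hi = ci$ci[2], flag = "")
  }))
  srl_sel <- clinical$lesion_size_cm <= 4.0
  srl <- if (sum(srl_sel) >= 2 && length(unique(labels[srl_sel])) == 2)
    metric_suite(risks[srl_sel], labels[srl_sel])
  else list(flag = "non-computable")
  structure(list(overall = metric_suite(risks, labels),
                 decision_curve = decision_curve(risks, labels),
                 subgroups = sub, srl = srl),
            class = "eval_report")
}

#' Write an evaluation report to JSON
#' @param report an `eval_report`.
#' @param path output path.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(rapply(unclass(report), unclass, how = "replace"),
                       path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
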