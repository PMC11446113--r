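test_that("AUC equals the scaled Mann-Whitney statistic with half ties", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  # complement symmetry for tie-free risks
  set.seed(3)
  r <- runif(50)
  y <- rbinom(50, 1, 0.5)
  expect_equal(roc_auc(r, y) + roc_auc(-r, y), 1)
  # invariance to case order
  o <- sample(50)
  expect_equal(roc_auc(r[o], y[o]), roc_auc(r, y))
})

test_that("DeLong variance matches independent oracles", {
  set.seed(7)
  r <- c(0.9, 0.8, 0.7, 0.65, 0.5, 0.45, 0.4, 0.3, 0.2, 0.1)
  y <- c(1, 1, 0, 1, 1, 0, 0, 1, 0, 0)
  ci <- delong_ci(r, y)
  # cross-check against pROC's DeLong implementation
  pr <- pROC::roc(y, r, direction = "<", quiet = TRUE)
  expect_equal(ci$auc, as.numeric(pROC::auc(pr)))
  expect_equal(ci$ci, as.numeric(pROC::ci.auc(pr, method = "delong"))[c(1, 3)],
               tolerance = 1e-9)
  # bootstrap oracle for the variance (2000 case resamples)
  boot <- replicate(2000, {
    i <- sample(10, replace = TRUE)
    if (length(unique(y[i])) < 2) NA_real_ else roc_auc(r[i], y[i])
  })
  expect_lt(abs(var(boot, na.rm = TRUE) - ci$se^2) / ci$se^2, 0.25)
  # paired test against pROC, and the self-comparison degenerate case
  r2 <- plogis(qlogis(r) + rnorm(10, 0, 0.5))
  dt <- delong_test(r, r2, y)
  pt <- pROC::roc.test(pROC::roc(y, r, direction = "<", quiet = TRUE),
                       pROC::roc(y, r2, direction = "<", quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(dt$p, pt$p.value, tolerance = 1e-9)
  expect_equal(delong_test(r, r, y)$p, 1)
})

test_that("DeLong confidence intervals cover at the nominal rate", {
  set.seed(19)
  hits <- 0
  width200 <- numeric(250)
  width800 <- numeric(250)
  for (i in 1:500) {
    y <- rep(c(0, 1), each = 100)
    r <- runif(200)
    ci <- delong_ci(r, y)
    if (ci$ci[1] <= 0.5 && ci$ci[2] >= 0.5) hits <- hits + 1
    if (i <= 250) {
      width200[i] <- diff(ci$ci)
      y8 <- rep(c(0, 1), each = 400)
      ci8 <- delong_ci(runif(800), y8)
      width800[i] <- diff(ci8$ci)
    }
  }
  expect_gt(hits / 500, 0.925)
  expect_lt(hits / 500, 0.975)
  # CI width shrinks roughly as n^(-1/2)
  expect_lt(mean(width800), 0.6 * mean(width200))
})

test_that("decile calibration handles exact fits, ties, and anti-fits", {
  # risks equal to within-bin observed rates: SSR = 0
  risks <- rep(c(0.2, 0.8), each = 50)
  set.seed(23)
  labels <- c(rep(c(1, 0), c(10, 40)), rep(c(1, 0), c(40, 10)))
  cal <- calibration_ssr(risks, labels)
  expect_equal(cal$ssr, 0)
  expect_equal(nrow(cal$table), 2)  # ties collapse to the two risk values
  # perfectly anti-calibrated 0/1 risks: two pure bins, SSR = 2
  y <- rep(c(0, 1), each = 50)
  cal2 <- calibration_ssr(1 - y, y)
  expect_equal(cal2$ssr, 2)
  # a well-calibrated simulation stays near zero at n = 600
  set.seed(29)
  r <- runif(600)
  yy <- rbinom(600, 1, r)
  cal3 <- calibration_ssr(r, yy)
  expect_equal(nrow(cal3$table), 10)
  expect_lt(cal3$ssr, 0.05)
  expect_equal(sum(cal3$table$n), 600)  # bins partition the cohort
})

test_that("net benefit obeys its algebraic identities", {
  set.seed(31)
  y <- rbinom(100, 1, 0.3)
  prev <- mean(y)
  # perfect classifier: NB = prevalence at every threshold
  dc <- decision_curve(as.numeric(y), y, thresholds = c(0.1, 0.5, 0.9))
  expect_equal(dc$net_benefit, rep(prev, 3))
  # treat-all at pt = prevalence: NB = 0 exactly
  dc2 <- decision_curve(runif(100), y, thresholds = prev)
  expect_equal(dc2$treat_all, 0)
  # worked 10-case set at pt = 0.3 against direct counting
  r10 <- c(0.9, 0.8, 0.6, 0.55, 0.4, 0.35, 0.2, 0.15, 0.1, 0.05)
  y10 <- c(1, 1, 0, 1, 0, 1, 0, 0, 1, 0)
  dc3 <- decision_curve(r10, y10, thresholds = 0.3)
  tp <- sum(r10 >= 0.3 & y10 == 1)
  fp <- sum(r10 >= 0.3 & y10 == 0)
  expect_equal(dc3$net_benefit, tp / 10 - fp / 10 * 0.3 / 0.7)
  # model NB never exceeds prevalence
  rr <- runif(100)
  dcr <- decision_curve(rr, y)
  expect_true(all(dcr$net_benefit <= prev + 1e-12))
  expect_error(decision_curve(rr, y, thresholds = 1), "within")
})

test_that("anchored cutoffs equal an exhaustive threshold scan", {
  set.seed(37)
  r <- round(runif(20), 3)
  y <- rbinom(20, 1, plogis(4 * (r - 0.5)))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  cut <- find_cutoffs(r, y)
  # brute force over every observed threshold
  scan <- function(target, kind) {
    cands <- sort(unique(r))
    ok <- vapply(cands, function(t) {
      if (kind == "sens") mean(r[y == 1] >= t) >= target
      else mean(r[y == 0] < t) >= target
    }, TRUE)
    if (!any(ok)) return(NA_real_)
    if (kind == "sens") max(cands[ok]) else min(cands[ok])
  }
  expect_equal(cut$sens99, scan(0.99, "sens"))
  expect_equal(cut$sens95, scan(0.95, "sens"))
  expect_equal(cut$spec95, scan(0.95, "spec"))
  expect_equal(cut$spec99, scan(0.99, "spec"))
  # 100% sensitivity threshold cannot exceed the smallest malignant risk
  cut100 <- find_cutoffs(r, y, sens_targets = 1)
  expect_lte(cut100$sens100, min(r[y == 1]))
  # perfectly separated risks: all four cutoffs inside the gap
  rs <- c(rep(0.2, 5), rep(0.8, 5))
  ys <- rep(c(0, 1), each = 5)
  cuts <- unlist(find_cutoffs(rs, ys))
  expect_true(all(cuts > 0.2 & cuts <= 0.8))
  # ordering invariant when all targets are attainable
  expect_true(cut$sens99 <= cut$sens95 || is.na(cut$sens99))
})

test_that("stratified reports mirror the unstratified suite", {
  set.seed(41)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  r <- plogis(qlogis(0.5) + 1.5 * (y - 0.5) + rnorm(n, 0, 0.8))
  clin <- data.frame(age = sample(30:80, n, TRUE),
                     gender = sample(c("male", "female"), n, TRUE),
                     lesion_size_cm = runif(n, 1, 8),
                     ct_report = sample(ct_categories(), n, TRUE))
  rep_all <- stratified_report(r, y, clin)
  expect_s3_class(rep_all, "eval_report")
  expect_equal(rep_all$overall$auc, roc_auc(r, y))
  # a subgroup equal to the whole cohort reproduces the overall metrics
  clin2 <- clin
  clin2$lesion_size_cm <- rep(2, n)  # everyone is an SRL
  rep2 <- stratified_report(r, y, clin2)
  expect_equal(rep2$srl$auc, rep2$overall$auc)
  expect_equal(rep2$srl$calibration$ssr, rep2$overall$calibration$ssr)
  # size-independent signal: SRL and whole-cohort AUC agree closely
  srl_auc <- rep_all$srl$auc
  expect_lt(abs(srl_auc - rep_all$overall$auc), 0.05)
  # an empty subgroup is flagged but the report is still emitted
  clin3 <- clin
  clin3$ct_report <- sample(c("malignant", "benign"), n, TRUE)
  rep3 <- stratified_report(r, y, clin3)
  eq_row <- rep3$subgroups[rep3$subgroups$subgroup == "ct_equivocal", ]
  expect_equal(eq_row$flag, "non-computable")
  expect_true(is.na(eq_row$auc))
  # metrics invariant to case order
  o <- sample(n)
  rep_o <- stratified_report(r[o], y[o], clin[o, ])
  expect_equal(rep_o$overall$auc, rep_all$overall$auc)
  expect_equal(rep_o$overall$calibration$ssr,
               rep_all$overall$calibration$ssr)
})
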