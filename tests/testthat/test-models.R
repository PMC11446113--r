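# Small informative tabular cohort for classifier tests (no imaging).
toy_cohort <- function(n = 200, p_info = 4, p_noise = 6, seed = 77) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- cbind(matrix(rnorm(n * p_info, mean = outer(y, rep(1.0, p_info))),
                    n, p_info),
             matrix(rnorm(n * p_noise), n, p_noise))
  tab <- as.data.frame(X)
  names(tab) <- sprintf("f%02d", seq_len(ncol(tab)))
  tab <- cbind(case_id = sprintf("c%03d", seq_len(n)), tab,
               stringsAsFactors = FALSE)
  list(table = tab, labels = y)
}

test_that("date-based splitting is deterministic and proportional", {
  clin <- data.frame(case_id = sprintf("c%03d", 1:100),
                     surgery_date = 1:100)
  sp <- split_by_date(clin, 0.66)
  expect_length(sp$development, 66)
  expect_length(sp$test, 34)
  expect_equal(sp$development, clin$case_id[1:66])
  # shuffled row order gives the identical split
  sp2 <- split_by_date(clin[sample(1:100), ], 0.66)
  expect_identical(sp, sp2)
  expect_error(split_by_date(clin, 1.0), "test")
  expect_error(split_by_date(clin, 0), "fraction")
})

test_that("classifiers separate a separable toy set and are reproducible", {
  # linearly separable two-feature set with a clear margin
  set.seed(44)
  x1 <- runif(80, -1, 1)
  x2 <- runif(80, -1, 1)
  ysep <- as.integer(x1 + x2 > 0)
  keep <- abs(x1 + x2) > 0.2
  sep_tab <- data.frame(case_id = sprintf("s%03d", seq_len(sum(keep))),
                        f1 = x1[keep], f2 = x2[keep])
  spec <- model_spec("logistic", "toy", seed = 3)
  m <- suppressWarnings(fit_model(spec, sep_tab, ysep[keep]))
  expect_equal(roc_auc(m$train_risks, ysep[keep]), 1.0)
  tc <- toy_cohort(80, p_info = 2, p_noise = 0)
  # re-passing training rows reproduces the stored fitted values
  m2 <- suppressWarnings(fit_model(spec, tc$table, tc$labels))
  expect_equal(predict_risk(m2, tc$table), m2$train_risks)

  es <- model_spec("stacked_ensemble", "toy", seed = 5)
  e1 <- suppressWarnings(fit_model(es, tc$table, tc$labels))
  e2 <- suppressWarnings(fit_model(es, tc$table, tc$labels))
  expect_identical(e1$train_risks, e2$train_risks)
  expect_true(all(e1$train_risks >= 0 & e1$train_risks <= 1))
})

test_that("prediction aligns columns by name and imputes missing cells", {
  tc <- toy_cohort(120)
  es <- model_spec("stacked_ensemble", "toy", seed = 9)
  m <- suppressWarnings(fit_model(es, tc$table, tc$labels))
  # column-permuted table scores identically
  perm <- tc$table[, c("case_id", sample(setdiff(names(tc$table),
                                                 "case_id")))]
  expect_equal(predict_risk(m, perm), m$train_risks)
  # missing cells fall back to training medians, probability stays in (0,1)
  one <- tc$table[1, ]
  one[, -1] <- NA
  p <- predict_risk(m, one)
  expect_true(p > 0 && p < 1)
  # absent manifest columns are an error
  expect_error(predict_risk(m, tc$table[, 1:4]), "missing")
})

test_that("stacked ensemble is competitive with its best base learner", {
  tc <- toy_cohort(240, seed = 31)
  tr <- 1:160
  te <- 161:240
  es <- model_spec("stacked_ensemble", "toy", seed = 11)
  m <- suppressWarnings(fit_model(es, tc$table[tr, ], tc$labels[tr]))
  ens_auc <- roc_auc(predict_risk(m, tc$table[te, ]), tc$labels[te])
  X <- renorad:::prepare_design(tc$table[tr, ])$X
  Xte <- renorad:::prepare_design(tc$table[te, ])$X
  base_aucs <- vapply(renorad:::base_learner_roster(), function(b) {
    set.seed(11)
    fb <- renorad:::fit_base(b, X, tc$labels[tr], 11)
    roc_auc(renorad:::predict_base(b, fb, Xte), tc$labels[te])
  }, 0)
  expect_gte(ens_auc, max(base_aucs) - 0.01)
})

test_that("no evaluation case was seen by the model that scored it", {
  spec <- phantom_spec(n_cases = 40, seed = 61)
  coh <- generate_cohort(spec, clinical_only = TRUE)
  sp <- split_by_date(coh$clinical, 0.66)
  dev <- coh$clinical$case_id %in% sp$development
  clin_tab <- renorad:::clinical_feature_table(coh$clinical)
  m <- fit_model(model_spec("logistic", "clinical", seed = 2),
                 clin_tab[dev, ], coh$labels[dev])
  expect_length(intersect(m$train_ids, sp$test), 0)
  risks <- predict_risk(m, clin_tab)
  expect_true(all(risks >= 0 & risks <= 1))
})

test_that("univariate logistic recovers the configured clinical log-odds", {
  spec <- phantom_spec(n_cases = 1500, seed = 71)
  coh <- generate_cohort(spec, clinical_only = TRUE)
  fit <- glm(label ~ I(gender == "male"), data = coh$clinical,
             family = binomial())
  est <- coef(summary(fit))[2, ]
  expect_lt(abs(est["Estimate"] - 1.6), 2 * est["Std. Error"])
})

test_that("risk fusion with the CT report behaves at the edge cases", {
  set.seed(91)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  risk <- plogis(qlogis(0.5) + 2 * (y - 0.5) + rnorm(n))
  dev <- seq_len(n) <= 200
  # constant CT category adds nothing: fusion AUC equals risk-alone AUC
  fu0 <- suppressWarnings(
    fuse_with_ct_report(risk, rep("equivocal", n), y, dev))
  p0 <- predict_fusion(fu0, risk, rep("equivocal", n))
  expect_equal(roc_auc(p0[!dev], y[!dev]), roc_auc(risk[!dev], y[!dev]))
  # oracle CT category gives a perfect fusion
  ct_oracle <- ifelse(y == 1, "malignant", "benign")
  fu1 <- suppressWarnings(fuse_with_ct_report(risk, ct_oracle, y, dev))
  p1 <- predict_fusion(fu1, risk, ct_oracle)
  expect_equal(roc_auc(p1[!dev], y[!dev]), 1.0)
  # 15% CT error: fusion is no worse than either input (small slack)
  ct_noisy <- ifelse(runif(n) < 0.15,
                     ifelse(y == 1, "benign", "malignant"), ct_oracle)
  fu2 <- suppressWarnings(fuse_with_ct_report(risk, ct_noisy, y, dev))
  p2 <- predict_fusion(fu2, risk, ct_noisy)
  ct_num <- (ct_noisy == "malignant") + 0.5 * (ct_noisy == "equivocal")
  expect_gte(roc_auc(p2[!dev], y[!dev]),
             max(roc_auc(risk[!dev], y[!dev]),
                 roc_auc(ct_num[!dev], y[!dev])) - 0.01)
})
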