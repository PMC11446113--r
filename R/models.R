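#' Model specification
#'
#' @param kind one of `"logistic"`, `"lasso"`, `"stacked_ensemble"`.
#' @param feature_block label recorded in the model manifest (e.g.
#'   `"clinical"`, `"ct_report"`, `"radiomics_ith"`, `"combined"`).
#' @param cv_folds stratified cross-validation folds (default 5, >= 2).
#' @param seed integer seed.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(kind = c("stacked_ensemble", "logistic", "lasso"),
                       feature_block = "radiomics_ith", cv_folds = 5L,
                       seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(cv_folds >= 2)
  structure(list(kind = kind, feature_block = feature_block,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "model_spec")
}

#' Development/test split by surgery date
#'
#' Orders cases by the date column (ties broken by `case_id`) and assigns
#' the earliest `fraction` to the development cohort, the remainder to the
#' test cohort.
#'
#' @param clinical data.frame with `case_id` and a sortable `surgery_date`
#'   (or `date`) column.
#' @param fraction development fraction in (0, 1).
#' @return list with `development` and `test` case-id vectors.
#' @export
split_by_date <- function(clinical, fraction = 0.66) {
  stopifnot(fraction > 0)
  if (fraction >= 1) stop("fraction must leave a non-empty test cohort")
  datecol <- intersect(c("surgery_date", "date"), names(clinical))[1]
  if (is.na(datecol)) stop("no sortable date column found")
  ord <- order(clinical[[datecol]], clinical$case_id)
  n_dev <- floor(fraction * nrow(clinical))
  if (n_dev < 1 || n_dev >= nrow(clinical))
    stop("degenerate split: fraction leaves an empty cohort")
  list(development = clinical$case_id[ord[seq_len(n_dev)]],
       test = clinical$case_id[ord[-seq_len(n_dev)]])
}

# Deterministic stratified fold assignment.
stratified_folds <- function(y, k, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    fold[i] <- sample(rep(seq_len(k), length.out = length(i)))
  }
  fold
}

# Design matrix: numeric feature columns, median-imputed. Column names are
# sanitized (deterministically, in column order) so downstream model-fitting
# formulas never see non-syntactic ROI names.
prepare_design <- function(table, medians = NULL) {
  feats <- feature_columns(table)
  X <- table[, feats, drop = FALSE]
  for (f in feats) {
    if (!is.numeric(X[[f]])) X[[f]] <- as.numeric(as.factor(X[[f]]))
  }
  X <- as.matrix(X)
  colnames(X) <- make.unique(make.names(feats))
  if (is.null(medians))
    medians <- apply(X, 2, function(col) median(col[is.finite(col)]))
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- medians[j]
  }
  list(X = X, medians = medians, orig_names = feats)
}

base_learner_roster <- function() {
  c("ridge", "rf", "extratrees", "xgb", "knn")
}

# glmnet needs >= 2 predictors; pad single-column designs with a constant.
pad2 <- function(X) if (ncol(X) < 2) cbind(X, `.pad` = 0) else X

# Penalized logistic fit with CV-chosen lambda when the minority class can
# sustain stratified folds (cv.glmnet needs >= 3), else a fixed penalty.
fit_glmnet_cv <- function(X, y, alpha, cv_folds, seed,
                          s_rule = "lambda.min", fallback_lambda = 0.01) {
  k <- min(cv_folds, min(table(y)))
  if (min(table(y)) < 2)  # degenerate inner fold: constant-risk model
    return(list(fit = NULL, s = mean(y)))
  if (k >= 3) {
    fit <- glmnet::cv.glmnet(pad2(X), y, family = "binomial",
                             alpha = alpha,
                             foldid = stratified_folds(y, k, seed),
                             type.measure = "deviance")
    list(fit = fit, s = s_rule)
  } else {
    list(fit = glmnet::glmnet(pad2(X), y, family = "binomial",
                              alpha = alpha),
         s = fallback_lambda)
  }
}

fit_base <- function(name, X, y, seed) {
  switch(name,
    ridge = fit_glmnet_cv(X, y, alpha = 0, cv_folds = 5L, seed = seed),
    rf = ranger::ranger(x = as.data.frame(X), y = factor(y),
                        probability = TRUE, num.trees = 300, seed = seed),
    extratrees = ranger::ranger(x = as.data.frame(X), y = factor(y),
                                probability = TRUE, num.trees = 300,
                                splitrule = "extratrees",
                                num.random.splits = 1, seed = seed),
    xgb = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3,
                    eta = 0.1, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y), nrounds = 100,
      verbose = 0),
    knn = list(train = X, cl = y, k = min(15L, nrow(X) - 1L)))
}

predict_base <- function(name, model, X) {
  p <- switch(name,
    ridge = if (is.null(model$fit)) rep(model$s, nrow(X)) else
      as.numeric(predict(model$fit, pad2(X), s = model$s,
                         type = "response")),
    rf = predict(model, as.data.frame(X))$predictions[, "1"],
    extratrees = predict(model, as.data.frame(X))$predictions[, "1"],
    xgb = as.numeric(predict(model, xgboost::xgb.DMatrix(X))),
    knn = {
      pr <- class::knn(model$train, X, factor(model$cl), k = model$k,
                       prob = TRUE)
      pw <- attr(pr, "prob")
      ifelse(pr == "1", pw, 1 - pw)
    })
  pmin(pmax(p, 1e-6), 1 - 1e-6)
}

#' Fit a classifier on the development cohort
#'
#' `"stacked_ensemble"`: five base learners (ridge-penalized logistic,
#' random forest, extremely randomized trees, gradient boosting, k-NN)
#' produce out-of-fold predictions under stratified `cv_folds`-fold CV; a
#' logistic meta-learner is fitted on those, and the base learners are then
#' refitted on the full development data. `"logistic"` is a plain GLM;
#' `"lasso"` is an L1-penalized comparator with lambda chosen by 5-fold CV
#' deviance under the 1-SE rule.
#'
#' @param spec a [model_spec()].
#' @param table development-cohort feature table (no test rows).
#' @param labels 0/1 vector aligned with the rows (both classes >= 2 cases).
#' @return fitted model object (class `renorad_model`) carrying the feature
#'   manifest, imputation medians, out-of-fold risks and the spec.
#' @export
fit_model <- function(spec, table, labels) {
  stopifnot(inherits(spec, "model_spec"),
            sum(labels == 0) >= 2, sum(labels == 1) >= 2)
  pd <- prepare_design(table)
  X <- pd$X
  y <- as.integer(labels)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  fitted <- switch(spec$kind,
    logistic = {
      df <- as.data.frame(X)
      list(glm = glm(y ~ ., data = cbind(df, y = y), family = binomial()))
    },
    lasso = {
      cv <- fit_glmnet_cv(X, y, alpha = 1, cv_folds = spec$cv_folds,
                          seed = spec$seed, s_rule = "lambda.1se",
                          fallback_lambda = 0.05)
      list(lasso = cv$fit, s = cv$s)
    },
    stacked_ensemble = {
      roster <- base_learner_roster()
      folds <- stratified_folds(y, spec$cv_folds, spec$seed)
      if (any(vapply(seq_len(spec$cv_folds), function(f)
        length(unique(y[folds != f])) < 2, TRUE))) {
        folds <- stratified_folds(y, spec$cv_folds, spec$seed + 1L)
        if (any(vapply(seq_len(spec$cv_folds), function(f)
          length(unique(y[folds != f])) < 2, TRUE)))
          stop("degenerate single-class folds")
      }
      oof <- matrix(NA_real_, nrow(X), length(roster),
                    dimnames = list(NULL, roster))
      for (f in seq_len(spec$cv_folds)) {
        tr <- folds != f
        for (b in roster) {
          set.seed(spec$seed + 97L * f + match(b, roster))
          m <- fit_base(b, X[tr, , drop = FALSE], y[tr], spec$seed + f)
          oof[!tr, b] <- predict_base(b, m, X[!tr, , drop = FALSE])
        }
      }
      # logistic meta-learner with non-negative stacking weights (the
      # classical constraint preventing sign-flips on small folds)
      meta <- glmnet::glmnet(qlogis(oof), y, family = "binomial",
                             alpha = 0, lambda = 1e-3, lower.limits = 0)
      base_full <- lapply(setNames(roster, roster), function(b) {
        set.seed(spec$seed + match(b, roster))
        fit_base(b, X, y, spec$seed)
      })
      list(meta = meta, base = base_full, oof = oof)
    })
  mod <- structure(list(spec = spec, fitted = fitted,
                        feature_names = pd$orig_names,
                        medians = pd$medians,
                        train_ids = table$case_id,
                        train_risks = NULL),
                   class = "renorad_model")
  mod$train_risks <- predict_risk(mod, table)
  mod
}

#' Predict malignancy risk
#'
#' Columns are aligned by name to the training manifest; missing cells are
#' imputed with training-set medians; unknown extra columns are an error
#' only when a manifest column is absent.
#'
#' @param model a [fit_model()] result.
#' @param table feature table to score.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_risk <- function(model, table) {
  feats <- feature_columns(table)
  miss <- setdiff(model$feature_names, feats)
  if (length(miss))
    stop("columns missing from table: ", paste(head(miss, 3), collapse = ", "))
  tab <- table[, c(intersect(names(table), "case_id"),
                   model$feature_names), drop = FALSE]
  X <- prepare_design(tab, medians = model$medians)$X
  f <- model$fitted
  p <- switch(model$spec$kind,
    logistic = as.numeric(predict(f$glm, as.data.frame(X),
                                  type = "response")),
    lasso = as.numeric(predict(f$lasso, pad2(X), s = f$s,
                               type = "response")),
    stacked_ensemble = {
      Z <- vapply(names(f$base), function(b)
        predict_base(b, f$base[[b]], X), numeric(nrow(X)))
      Z <- matrix(Z, nrow = nrow(X),
                  dimnames = list(NULL, names(f$base)))
      as.numeric(predict(f$meta, qlogis(Z), type = "response"))
    })
  pmin(pmax(p, 0), 1)
}

#' Fuse model risk with the CT-reported category
#'
#' Logistic regression of the label on the predicted risk plus a one-hot
#' encoding of the CT report, trained on development cases only. A category
#' absent from the development set is collapsed into the nearest ordinal
#' category (benign < equivocal < malignant) with a warning.
#'
#' @param risks per-case predicted risk.
#' @param ct_categories character vector in
#'   `c("malignant", "equivocal", "benign")`.
#' @param labels 0/1 vector.
#' @param dev logical vector (or index) marking development cases.
#' @return object of class `renorad_fusion` with a `predict` method via
#'   [predict_fusion()].
#' @export
fuse_with_ct_report <- function(risks, ct_categories, labels, dev) {
  stopifnot(all(ct_categories %in% c("malignant", "equivocal", "benign")))
  lev <- c("benign", "equivocal", "malignant")
  ct <- factor(ct_categories, levels = lev)
  dev <- if (is.logical(dev)) dev else seq_along(risks) %in% dev
  present <- lev[lev %in% unique(as.character(ct[dev]))]
  if (length(present) < length(lev)) {
    warning("CT categories absent from development set collapsed: ",
            paste(setdiff(lev, present), collapse = ", "))
    ord <- match(as.character(ct), lev)
    po <- match(present, lev)
    ct <- factor(present[vapply(ord, function(o)
      which.min(abs(po - o)), 0L)], levels = present)
  }
  df <- data.frame(y = as.integer(labels), risk = qlogis(
    pmin(pmax(risks, 1e-6), 1 - 1e-6)), ct = ct)
  form <- if (nlevels(droplevels(ct[dev])) >= 2) y ~ risk + ct else y ~ risk
  if (nlevels(droplevels(ct[dev])) < 2) ct <- droplevels(ct)
  fit <- glm(form, data = droplevels(df[dev, ]), family = binomial())
  structure(list(glm = fit, levels = levels(droplevels(ct[dev]))),
            class = "renorad_fusion")
}

#' @rdname fuse_with_ct_report
#' @param fusion a `renorad_fusion` object.
#' @export
predict_fusion <- function(fusion, risks, ct_categories) {
  ct <- factor(ct_categories, levels = fusion$levels)
  if (anyNA(ct)) {
    ord <- match(ct_categories, c("benign", "equivocal", "malignant"))
    po <- match(fusion$levels, c("benign", "equivocal", "malignant"))
    ct <- factor(fusion$levels[vapply(ord, function(o)
      which.min(abs(po - o)), 0L)], levels = fusion$levels)
  }
  df <- data.frame(risk = qlogis(pmin(pmax(risks, 1e-6), 1 - 1e-6)), ct = ct)
  as.numeric(predict(fusion$glm, df, type = "response"))
}

#' CT report categories
#' @return the category labels used throughout the package.
#' @export
ct_categories <- function() c("malignant", "equivocal", "benign")
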