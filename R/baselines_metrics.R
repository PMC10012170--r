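# ---------------------------------------------------------------------------
# QSAR baselines and the shared validation metric suite
# ---------------------------------------------------------------------------

#' Train/test split
#'
#' Random split with optional stratification by hazard class (proportional
#' allocation per class), deterministic given the seed.  With stratification
#' and tiny data a class can still end up absent from one side; this is a
#' warning, not an error.
#'
#' @param dataset data.frame.
#' @param fraction Training fraction in (0, 1).
#' @param stratify Stratify by the discretized viability outcome.
#' @param seed Integer seed.
#' @return List with `train`, `test` (data.frames) and `train_idx`,
#'   `test_idx` (row indices into `dataset`).
#' @export
split_dataset <- function(dataset, fraction = 0.8, stratify = TRUE,
                          seed = 1L) {
  stopifnot(fraction > 0, fraction < 1, nrow(dataset) >= 10L)
  set.seed(seed)
  n <- nrow(dataset)
  if (stratify && "viability" %in% names(dataset)) {
    cls <- if (is.factor(dataset$viability)) dataset$viability
           else classify_viability(dataset$viability)
    test_idx <- integer()
    for (lv in levels(cls)) {
      idx <- which(cls == lv)
      n_test <- round(length(idx) * (1 - fraction))
      if (length(idx) && n_test == 0L)
        warning("class '", lv, "' absent from the test split")
      test_idx <- c(test_idx, sample(idx, n_test))
    }
    test_idx <- sort(test_idx)
  } else {
    test_idx <- sort(sample(n, round(n * (1 - fraction))))
  }
  train_idx <- setdiff(seq_len(n), test_idx)
  list(train = dataset[train_idx, , drop = FALSE],
       test = dataset[test_idx, , drop = FALSE],
       train_idx = train_idx, test_idx = test_idx)
}

#' Deterministic k-fold assignment
#' @param n Number of rows.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold labels (1..k) partitioning `1:n`.
#' @export
cv_folds <- function(n, k = 10L, seed = 1L) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Regression error metrics
#'
#' @param y Observed values.
#' @param yhat Predictions.
#' @return List with `mae`, `rmse`, `r2` (`r2` is `NA` for constant `y`
#'   and may be negative on external data).
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  res <- y - yhat
  ss_tot <- sum((y - mean(y))^2)
  list(mae = mean(abs(res)),
       rmse = sqrt(mean(res^2)),
       r2 = if (ss_tot == 0) NA_real_ else 1 - sum(res^2) / ss_tot)
}

#' Multiclass classification metrics
#'
#' Per class (one-vs-rest): precision, recall, F1, and balanced accuracy
#' `(TPR + TNR) / 2`.  Two overall summaries are reported, reflecting the
#' two conventions in circulation: `balanced_accuracy` is the macro mean
#' of the per-class recalls (the scikit-learn convention), while
#' `mean_class_balanced_accuracy` is the macro mean of the per-class
#' `(TPR + TNR) / 2` values (the "average accuracy across hazard classes"
#' convention used when summarizing per-class validation panels).  The
#' Matthews correlation coefficient is the multiclass generalization
#' computed from the full confusion matrix.  Classes with zero support and
#' zero predictions are reported as `NA` and excluded from macro means.
#'
#' @param y Observed classes (factor or character).
#' @param yhat Predicted classes over the same state space.
#' @param levels Class levels (default: union of observed levels, in
#'   [hazard_classes()] order when applicable).
#' @return List of class `metrics_report` with `confusion` (rows = truth,
#'   cols = prediction), `per_class` data.frame, `balanced_accuracy`,
#'   `mcc`, `accuracy`, `macro_f1`, `n`.
#' @export
classification_metrics <- function(y, yhat, levels = NULL) {
  if (is.null(levels)) {
    levels <- if (is.factor(y)) base::levels(y)
              else sort(unique(c(as.character(y), as.character(yhat))))
    hz <- hazard_classes()
    if (all(levels %in% hz)) levels <- hz[hz %in% levels]
  }
  y <- factor(as.character(y), levels = levels)
  yhat <- factor(as.character(yhat), levels = levels)
  stopifnot(length(y) == length(yhat), !anyNA(y), !anyNA(yhat))
  cm <- table(truth = y, prediction = yhat)
  n <- sum(cm)
  per <- lapply(seq_along(levels), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- n - tp - fn - fp
    if ((tp + fn) == 0 && (tp + fp) == 0)
      return(data.frame(class = levels[[i]], support = 0,
                        precision = NA_real_, recall = NA_real_,
                        f1 = NA_real_, balanced_accuracy = NA_real_))
    prec <- if ((tp + fp) == 0) NA_real_ else tp / (tp + fp)
    rec <- if ((tp + fn) == 0) NA_real_ else tp / (tp + fn)
    tnr <- if ((tn + fp) == 0) NA_real_ else tn / (tn + fp)
    f1 <- if (is.na(prec) || is.na(rec) || (prec + rec) == 0) NA_real_
          else 2 * prec * rec / (prec + rec)
    data.frame(class = levels[[i]], support = tp + fn,
               precision = prec, recall = rec, f1 = f1,
               balanced_accuracy = (rec + tnr) / 2)
  })
  per <- do.call(rbind, per)
  # multiclass MCC from the full confusion matrix
  c_ <- sum(diag(cm)); s <- n
  p_k <- colSums(cm); t_k <- rowSums(cm)
  den <- sqrt((s^2 - sum(p_k^2)) * (s^2 - sum(t_k^2)))
  mcc <- if (den == 0) 0 else (c_ * s - sum(p_k * t_k)) / den
  structure(list(
    confusion = cm,
    per_class = per,
    balanced_accuracy = mean(per$recall, na.rm = TRUE),
    mean_class_balanced_accuracy =
      mean(per$balanced_accuracy, na.rm = TRUE),
    macro_f1 = mean(per$f1, na.rm = TRUE),
    accuracy = c_ / s,
    mcc = mcc,
    n = n
  ), class = "metrics_report")
}

# ---------------------------------------------------------------------------
# Baseline model sweep
# ---------------------------------------------------------------------------

fit_predict_reg <- function(model, train, test, outcome, seed) {
  x_cols <- setdiff(names(train), outcome)
  fx <- as.formula(paste0("`", outcome, "` ~ ."))
  set.seed(seed)
  switch(model,
    rfr = {
      fit <- randomForest::randomForest(
        x = train[x_cols], y = train[[outcome]], ntree = 300)
      predict(fit, test[x_cols])
    },
    etr = {
      fit <- ranger::ranger(x = train[x_cols], y = train[[outcome]],
                            num.trees = 300, splitrule = "extratrees",
                            num.random.splits = 1, seed = seed)
      predict(fit, test[x_cols])$predictions
    },
    gbr = {
      fit <- xgboost::xgboost(
        x = as.matrix(train[x_cols]), y = train[[outcome]],
        nrounds = 150, max_depth = 5, learning_rate = 0.1,
        objective = "reg:squarederror", verbosity = 0, nthreads = 1L)
      predict(fit, as.matrix(test[x_cols]))
    },
    lr = {
      fit <- stats::lm(fx, data = train)
      unname(predict(fit, test))
    },
    stop("unknown regression model '", model, "'"))
}

fit_predict_cls <- function(model, train, test, outcome, seed) {
  x_cols <- setdiff(names(train), outcome)
  fx <- as.formula(paste0("`", outcome, "` ~ ."))
  lev <- levels(train[[outcome]])
  set.seed(seed)
  pred <- switch(model,
    rf = {
      fit <- randomForest::randomForest(
        x = train[x_cols], y = train[[outcome]], ntree = 300)
      as.character(predict(fit, test[x_cols]))
    },
    et = {
      fit <- ranger::ranger(x = train[x_cols], y = train[[outcome]],
                            num.trees = 300, splitrule = "extratrees",
                            num.random.splits = 1, seed = seed)
      as.character(predict(fit, test[x_cols])$predictions)
    },
    gbc = {
      fit <- xgboost::xgboost(
        x = as.matrix(train[x_cols]), y = train[[outcome]],
        nrounds = 150, max_depth = 5, learning_rate = 0.1,
        verbosity = 0, nthreads = 1L)
      as.character(predict(fit, as.matrix(test[x_cols]),
                           type = "class"))
    },
    dt = {
      fit <- rpart::rpart(fx, data = train, method = "class")
      as.character(predict(fit, test, type = "class"))
    },
    stop("unknown classification model '", model, "'"))
  factor(pred, levels = lev)
}

baseline_sweep <- function(train, test, outcome, models, fitter, scorer,
                           cv_k, seed) {
  reports <- list()
  for (model in models) {
    folds <- cv_folds(nrow(train), k = cv_k, seed = seed)
    oof <- rep(NA, nrow(train))
    oof_chr <- rep(NA_character_, nrow(train))
    for (f in seq_len(cv_k)) {
      hold <- folds == f
      p <- fitter(model, train[!hold, , drop = FALSE],
                  train[hold, , drop = FALSE], outcome, seed + f)
      if (is.factor(p)) oof_chr[hold] <- as.character(p)
      else oof[hold] <- p
    }
    cv_metrics <- if (all(is.na(oof)))
      scorer(train[[outcome]],
             factor(oof_chr, levels = levels(train[[outcome]])))
    else scorer(train[[outcome]], oof)
    p_test <- fitter(model, train, test, outcome, seed)
    test_metrics <- scorer(test[[outcome]], p_test)
    reports[[model]] <- list(model = model, cv = cv_metrics,
                             test = test_metrics,
                             n_test = nrow(test))
  }
  reports
}

#' Fit the regression baseline set
#'
#' Random forest, extremely randomized trees, gradient-boosted trees and
#' ordinary linear regression on the numeric (one-hot encoded) feature
#' table, predicting viability (%).  Each model is scored by 10-fold
#' cross-validation on the training split (pooled out-of-fold predictions)
#' and externally on the untouched test split.
#'
#' @param train,test data.frames of numeric features plus a `viability`
#'   column.
#' @param models Subset of `c("rfr", "etr", "gbr", "lr")`.
#' @param cv_k Folds for internal cross-validation.
#' @param seed Integer seed.
#' @return Named list of per-model reports (`cv` and `test` metric lists).
#' @export
fit_regressors <- function(train, test,
                           models = c("rfr", "etr", "gbr", "lr"),
                           cv_k = 10L, seed = 1L) {
  stopifnot(all(vapply(train, is.numeric, NA)))
  if (any(!is.finite(as.matrix(train))) || any(!is.finite(as.matrix(test))))
    stop("non-finite feature values")
  baseline_sweep(train, test, "viability", models, fit_predict_reg,
                 regression_metrics, cv_k, seed)
}

#' Fit the classification baseline set
#'
#' Random forest, extremely randomized trees, gradient-boosted trees and a
#' single decision tree predicting the three-state hazard class.  Class
#' balancing (SMOTE) is expected to have been applied to the training split
#' only, upstream.
#'
#' @param train,test data.frames of numeric features plus a factor
#'   `viability` column holding hazard classes.
#' @param models Subset of `c("rf", "et", "gbc", "dt")`.
#' @param cv_k Folds for internal cross-validation.
#' @param seed Integer seed.
#' @return Named list of per-model reports (`cv` and `test`
#'   `metrics_report`s).
#' @export
fit_classifiers <- function(train, test,
                            models = c("rf", "et", "gbc", "dt"),
                            cv_k = 10L, seed = 1L) {
  stopifnot(is.factor(train$viability), is.factor(test$viability))
  baseline_sweep(train, test, "viability", models, fit_predict_cls,
                 classification_metrics, cv_k, seed)
}

#' Flatten baseline reports into a leaderboard table
#'
#' @param reports Result of [fit_regressors()] or [fit_classifiers()].
#' @return data.frame, one row per model x evaluation (cv / test).
#' @export
leaderboard <- function(reports) {
  rows <- list()
  for (model in names(reports)) {
    for (eval in c("cv", "test")) {
      m <- reports[[model]][[eval]]
      row <- if (inherits(m, "metrics_report"))
        data.frame(model = model, eval = eval,
                   balanced_accuracy = m$balanced_accuracy,
                   macro_f1 = m$macro_f1, mcc = m$mcc,
                   accuracy = m$accuracy)
      else
        data.frame(model = model, eval = eval,
                   mae = m$mae, rmse = m$rmse, r2 = m$r2)
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
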