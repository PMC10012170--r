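test_that("splits are disjoint, exhaustive and stratified proportionally", {
  d <- data.frame(x = rnorm(100),
                  viability = c(rep(90, 60), rep(50, 30), rep(10, 10)))
  sp <- split_dataset(d, fraction = 0.8, stratify = TRUE, seed = 3L)
  expect_equal(nrow(sp$train), 80L)
  expect_equal(nrow(sp$test), 20L)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:100)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  cls_test <- classify_viability(d$viability[sp$test_idx])
  expect_equal(unname(table(cls_test)), c(2L, 6L, 12L),
               ignore_attr = TRUE)   # very_toxic, toxic, safe
  # determinism
  sp2 <- split_dataset(d, fraction = 0.8, stratify = TRUE, seed = 3L)
  expect_identical(sp$test_idx, sp2$test_idx)
})

test_that("regression metrics match hand computations and Jensen's
          inequality", {
  m <- regression_metrics(c(3, 7, 1), c(3, 7, 1))
  expect_equal(unlist(m), c(mae = 0, rmse = 0, r2 = 1))
  m2 <- regression_metrics(c(0, 10), c(5, 5))
  expect_equal(m2$mae, 5)
  expect_equal(m2$rmse, 5)
  expect_equal(m2$r2, 0)
  set.seed(41)
  for (i in 1:20) {
    y <- rnorm(30); yh <- rnorm(30)
    m3 <- regression_metrics(y, yh)
    expect_gte(m3$rmse, m3$mae)
  }
  # a train-mean predictor can never beat R^2 = 0 on its own data
  y <- rnorm(50)
  expect_lte(regression_metrics(y, rep(mean(y), 50))$r2, 0)
})

test_that("classification metrics follow the one-vs-rest reading of the
          confusion matrix", {
  lev <- hazard_classes()
  y <- factor(rep(lev, each = 10), levels = lev)
  expect_equal(classification_metrics(y, y)$balanced_accuracy, 1)
  expect_equal(classification_metrics(y, y)$mcc, 1)

  # rows(true) x cols(pred) = [[8,2,0],[1,6,3],[0,2,8]]
  cm <- matrix(c(8, 2, 0, 1, 6, 3, 0, 2, 8), nrow = 3, byrow = TRUE)
  yy <- rep(lev, rowSums(cm))
  yh <- unlist(lapply(1:3, function(i) rep(lev, cm[i, ])))
  m <- classification_metrics(yy, yh, levels = lev)
  tox <- m$per_class[m$per_class$class == "toxic", ]
  expect_equal(tox$recall, 0.6)
  expect_equal(tox$precision, 0.6)
  expect_equal(m$balanced_accuracy,
               mean(c(8 / 10, 6 / 10, 8 / 10)))

  # permuting class labels permutes per-class metrics, MCC unchanged
  perm <- c(very_toxic = "safe", toxic = "very_toxic", safe = "toxic")
  mp <- classification_metrics(perm[yy], perm[yh],
                               levels = c("safe", "very_toxic", "toxic"))
  expect_equal(mp$mcc, m$mcc)
  expect_equal(sort(mp$per_class$recall), sort(m$per_class$recall))
})

test_that("multiclass MCC reduces to the binary formula on two classes", {
  set.seed(42)
  y <- sample(c("pos", "neg"), 60, TRUE)
  yh <- ifelse(runif(60) < 0.75, y, sample(c("pos", "neg"), 60, TRUE))
  m <- classification_metrics(y, yh, levels = c("neg", "pos"))
  tp <- sum(y == "pos" & yh == "pos"); tn <- sum(y == "neg" & yh == "neg")
  fp <- sum(y == "neg" & yh == "pos"); fn <- sum(y == "pos" & yh == "neg")
  bin <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(m$mcc, bin)
})

test_that("tree ensembles learn a trivially learnable regression signal", {
  set.seed(43)
  n <- 200
  d <- data.frame(x1 = runif(n), x2 = rnorm(n))
  d$viability <- 100 * d$x1
  sp <- split_dataset(d, stratify = FALSE, seed = 5L)
  reps <- fit_regressors(sp$train, sp$test, models = c("rfr", "gbr"),
                         cv_k = 5L, seed = 6L)
  expect_gt(max(vapply(reps, function(r) r$test$r2, 0)), 0.99)
  expect_equal(reps$rfr$n_test, nrow(sp$test))
})

test_that("classifiers separate well-separated classes perfectly and
          stay inside the known state space", {
  set.seed(44)
  n <- 150
  cls <- factor(sample(hazard_classes(), n, TRUE),
                levels = hazard_classes())
  d <- data.frame(x1 = as.integer(cls) * 10 + rnorm(n, 0, 0.1),
                  x2 = rnorm(n))
  d$viability <- cls
  idx <- sample(n, 120)
  train <- d[idx, ]; test <- d[-idx, ]
  reps <- fit_classifiers(train, test, models = c("rf", "dt"),
                          cv_k = 5L, seed = 7L)
  expect_equal(reps$rf$test$balanced_accuracy, 1)
  expect_true(all(levels(train$viability) %in% hazard_classes()))
  lb <- leaderboard(reps)
  expect_equal(nrow(lb), 4L)
  expect_setequal(unique(lb$eval), c("cv", "test"))
})

test_that("cross-validation folds partition the training rows
          deterministically", {
  f1 <- cv_folds(97, k = 10, seed = 9L)
  f2 <- cv_folds(97, k = 10, seed = 9L)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:10)
  expect_true(all(table(f1) %in% c(9L, 10L)))
})
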