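#!/usr/bin/env Rscript
# Stage 4: QSAR baselines.  Regressors predict viability (%); classifiers
# predict the hazard class after SMOTE balancing of the training split.
# 10-fold internal cross-validation on the 80% split, external metrics on
# the untouched 20%.

suppressMessages(library(hazardbn))

final <- read.csv("results/02_final_features.csv", stringsAsFactors = FALSE)
sp <- split_dataset(final, fraction = 0.8, stratify = TRUE, seed = 7L)

cat_cols <- c("coating", "cell_line", "assay")
enc_train <- one_hot(sp$train, columns = cat_cols)
enc_test <- one_hot(sp$test, columns = cat_cols,
                    levels = attr(enc_train, "one_hot_levels"))

reg <- fit_regressors(enc_train, enc_test, seed = 17L)

x_train <- enc_train; x_train$viability <- NULL
bal <- smote_oversample(as.matrix(x_train),
                        classify_viability(sp$train$viability),
                        seed = 11L)
cls_train <- as.data.frame(bal$features)
cls_train$viability <- bal$labels
cls_test <- enc_test
cls_test$viability <- classify_viability(sp$test$viability)
cls <- fit_classifiers(cls_train, cls_test, seed = 17L)

lb_reg <- cbind(task = "regression", leaderboard(reg))
lb_cls <- cbind(task = "classification", leaderboard(cls))
write.csv(lb_reg, "results/04_leaderboard_regression.csv",
          row.names = FALSE)
write.csv(lb_cls, "results/04_leaderboard_classification.csv",
          row.names = FALSE)

cat("external regression metrics (20% hold-out):\n")
ext <- lb_reg[lb_reg$eval == "test", ]
print(ext[order(ext$rmse), c("model", "mae", "rmse", "r2")],
      row.names = FALSE, digits = 3)
cat("external classification metrics (20% hold-out):\n")
extc <- lb_cls[lb_cls$eval == "test", ]
print(extc[order(-extc$balanced_accuracy),
           c("model", "balanced_accuracy", "macro_f1", "mcc")],
      row.names = FALSE, digits = 3)
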