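make_stratum <- function(erm = "E1", cell = "A549", pre = "none",
                         dose, hydro) {
  data.frame(erm_id = erm, cell_line = cell, pretreatment = pre,
             dose = dose, hydro_size_t0 = hydro,
             stringsAsFactors = FALSE)
}

test_that("strata interpolation fills in-range gaps and nothing else", {
  d <- rbind(
    make_stratum(dose = c(10, 20, 50, 5), hydro = c(100, NA, 200, NA)),
    make_stratum(pre = "digested", dose = 50, hydro = 300),
    make_stratum(pre = "non-digested", dose = c(50, 20),
                 hydro = c(NA, NA)))
  out <- interpolate_strata(d, columns = "hydro_size_t0")
  # 100 + (20-10)/(50-10) * 100 = 125
  expect_equal(out$hydro_size_t0[[2L]], 125)
  # below the smallest known dose: left blank
  expect_true(is.na(out$hydro_size_t0[[4L]]))
  # the digested stratum never fills the non-digested one
  expect_true(all(is.na(out$hydro_size_t0[6:7])))
  # observed cells untouched
  expect_equal(out$hydro_size_t0[c(1, 3, 5)], c(100, 200, 300))
})

test_that("chained imputation is an identity on complete data and learns
          collinear structure", {
  cfg <- small_generator(seed = 12L)
  cfg$missing_rates <- c(hydro_size_t0 = 0)
  d <- generate_dataset(cfg)
  expect_identical(iterative_impute(d), d)

  # plant y = 2 x exactly: pdi_t24 = 2 * pdi_t0, blank one cell
  d2 <- d
  d2$pdi_t24 <- 2 * d2$pdi_t0
  d2$pdi_t24[[17L]] <- NA
  imp <- iterative_impute(d2, seed = 5L)
  truth <- 2 * d2$pdi_t0[[17L]]
  expect_lt(abs(imp$pdi_t24[[17L]] - truth) / truth, 0.05)

  # postcondition: no missing numeric inputs remain
  d3 <- generate_dataset(small_generator(seed = 13L))
  imp3 <- iterative_impute(interpolate_strata(d3), seed = 6L)
  num <- intersect(c("hydro_size_t0", "hydro_size_t24", "pdi_t0",
                     "pdi_t24", "spherical_surface_area"), names(imp3))
  expect_equal(sum(is.na(imp3[num])), 0L)
})

test_that("imputation refuses a column with nothing observed", {
  d <- generate_dataset(small_generator(seed = 14L))
  d$pdi_t0 <- NA_real_
  expect_error(iterative_impute(d), "entirely missing")
})

test_that("feature finalization yields the 15 modeling inputs plus the
          outcome", {
  d <- generate_dataset(small_generator(seed = 15L))
  d <- iterative_impute(interpolate_strata(d))
  fin <- finalize_features(d)
  expect_setequal(names(fin), c(final_feature_columns(), "viability"))
  expect_equal(ncol(fin), 16L)
  expect_false("organ" %in% names(fin))
  expect_false("pretreatment" %in% names(fin))
  expect_true("assay" %in% names(fin))
})

test_that("one-hot encoding produces sorted 0/1 indicators and is
          invertible", {
  d <- data.frame(coating = c("HEC", "CUR", "none", "PVP", "HEC"),
                  x = 1:5)
  enc <- one_hot(d, columns = "coating")
  ind_cols <- c("coating=CUR", "coating=HEC", "coating=PVP",
                "coating=none")
  expect_true(all(ind_cols %in% names(enc)))
  expect_equal(unname(unlist(enc[1L, ind_cols])), c(0, 1, 0, 0))
  expect_true(all(rowSums(enc[ind_cols]) == 1))
  expect_equal(one_hot_decode(enc, "coating"), d$coating)
  # unseen state at apply time
  d2 <- data.frame(coating = "PEG", x = 1)
  expect_error(one_hot(d2, columns = "coating",
                       levels = list(coating = c("HEC", "PVP"))), "PEG")
})

test_that("SMOTE balances classes exactly and interpolates within class", {
  set.seed(31)
  X <- matrix(rnorm(40 * 3), ncol = 3)
  y <- factor(rep(c("safe", "toxic", "very_toxic"), c(25, 10, 5)),
              levels = hazard_classes())
  out <- smote_oversample(X, y, seed = 7L)
  expect_true(all(table(out$labels) == 25L))
  # originals preserved verbatim, first
  expect_equal(out$features[1:40, ], X, ignore_attr = TRUE)
  # synthetic rows stay inside their class's bounding box
  syn <- out$features[-(1:40), ]
  syn_lab <- out$labels[-(1:40)]
  for (cl in c("toxic", "very_toxic")) {
    cls_rows <- X[y == cl, , drop = FALSE]
    s <- syn[syn_lab == cl, , drop = FALSE]
    for (j in 1:3) {
      expect_true(all(s[, j] >= min(cls_rows[, j]) - 1e-12))
      expect_true(all(s[, j] <= max(cls_rows[, j]) + 1e-12))
    }
  }
  # balanced input returned unchanged
  yb <- factor(rep(c("safe", "toxic"), each = 10),
               levels = c("safe", "toxic"))
  outb <- smote_oversample(X[1:20, ], yb, seed = 8L)
  expect_equal(outb$features, X[1:20, ], ignore_attr = TRUE)
  expect_error(smote_oversample(X, factor(c(rep("a", 39), "b"))),
               "single member")
})

test_that("a two-member minority yields synthetics exactly on the
          segment", {
  X <- rbind(matrix(rnorm(20), ncol = 2),
             c(0, 0), c(2, 4))
  y <- factor(c(rep("maj", 10), "min", "min"))
  out <- smote_oversample(X, y, seed = 9L)
  syn <- out$features[-(1:12), , drop = FALSE]
  # on the segment (0,0)-(2,4): y = 2 x, 0 <= x <= 2
  expect_equal(syn[, 2], 2 * syn[, 1])
  expect_true(all(syn[, 1] >= 0 & syn[, 1] <= 2))
})

test_that("tercile bins split a uniform grid 3/3/3 and use left-closed
          edges", {
  d <- data.frame(dose = as.numeric(1:9))
  map <- fit_quantile_bins(d, columns = "dose")
  binned <- bin_values(d$dose, map$dose)
  expect_equal(unname(table(binned)), c(3L, 3L, 3L), ignore_attr = TRUE)
  expect_error(fit_quantile_bins(data.frame(x = rep(1, 10)),
                                 columns = "x"), "degenerate.*x")
  # edge ownership: value below e1 -> low, equal to e1 -> medium,
  # equal to e2 -> high
  spec <- list(edges = c(20, 58.35), range = c(0, 100),
               labels = c("low", "medium", "high"))
  expect_equal(as.character(bin_values(c(5, 20, 58.35, 99), spec)),
               c("low", "medium", "high", "high"))
  expect_equal(as.character(bin_values(-3, spec)), "low")
})

test_that("bin counts on generated data are near-equal up to ties", {
  d <- generate_dataset(generator_config(seed = 16L))
  d <- iterative_impute(interpolate_strata(d), seed = 7L)
  fin <- finalize_features(d)
  map <- fit_quantile_bins(fin)
  n <- nrow(fin)
  for (col in c("hydro_size_t0", "pdi_t24")) {
    counts <- table(bin_values(fin[[col]], map[[col]]))
    ties <- max(table(fin[[col]]))
    expect_true(all(abs(counts - n / 3) <= ties + 1))
  }
  # the fully discretized table has no missing cells
  binned <- apply_bins(fin, map)
  expect_false(anyNA(binned))
  expect_s3_class(binned$viability, "factor")
})
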