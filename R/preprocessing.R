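# ---------------------------------------------------------------------------
# Preprocessing: interpolation, chained imputation, encoding, balancing,
# discretization
# ---------------------------------------------------------------------------

#' Dose-wise linear interpolation within experimental strata
#'
#' Fills missing system-dependent values by linear interpolation over dose,
#' strictly within a stratum defined by (erm_id, cell_line, pretreatment):
#' a missing value at dose d is filled only when the variable is known at a
#' smaller and a larger dose in the same stratum; values outside the known
#' dose range stay missing, and nothing ever crosses strata.  Observed
#' cells are never altered.  Replicate observations at the same dose are
#' averaged to form the interpolation anchors.
#'
#' @param dataset data.frame in canonical schema (must contain `dose`).
#' @param columns Columns to interpolate (default: the four DLS columns
#'   present in the dataset).
#' @return The dataset with in-range gaps filled.
#' @export
interpolate_strata <- function(dataset,
                               columns = intersect(dls_columns(),
                                                   names(dataset))) {
  stopifnot("dose" %in% names(dataset))
  key_cols <- intersect(c("erm_id", "cell_line", "pretreatment"),
                        names(dataset))
  key <- do.call(paste, c(dataset[key_cols], sep = "\r"))
  for (col in columns) {
    for (k in unique(key)) {
      idx <- which(key == k)
      v <- dataset[[col]][idx]
      d <- dataset$dose[idx]
      known <- !is.na(v)
      if (sum(known) < 2L || !any(!known)) next
      anchors <- aggregate(list(y = v[known]), list(x = d[known]), mean)
      if (nrow(anchors) < 2L) next
      miss <- which(!known)
      filled <- approx(anchors$x, anchors$y, xout = d[miss],
                       method = "linear", rule = 1)$y
      dataset[[col]][idx[miss]] <- filled
    }
  }
  dataset
}

# one-hot design matrix used internally by the imputer (identifier kept as
# a predictor so nanoform-specific values are learnable)
impute_design <- function(dataset, exclude) {
  sc <- dataset_schema()
  num <- intersect(schema_columns("numeric_input"), names(dataset))
  cat <- intersect(c(schema_columns("categorical_input"), "erm_id"),
                   names(dataset))
  num <- setdiff(num, exclude)
  mats <- list()
  for (col in num) mats[[col]] <- dataset[[col]]
  X <- do.call(cbind, mats)
  for (col in cat) {
    states <- sort(unique(dataset[[col]]))
    for (s in states) {
      X <- cbind(X, as.numeric(dataset[[col]] == s))
      colnames(X)[ncol(X)] <- paste0(col, "=", s)
    }
  }
  X
}

#' Iterative chained imputation with gradient-boosted trees
#'
#' Fills every remaining missing numeric input by chained regression: each
#' incomplete column is modelled as a function of all other features
#' (including the ERM identifier, one-hot encoded, which fragments the data
#' into nanoform-specific groups) with a gradient-boosted tree regressor.
#' Columns are visited in order of ascending missingness, initialized from
#' column medians, cycling until `max_iter` sweeps or until the largest
#' absolute change of any imputed cell, in standardized units, drops to
#' `tol`.
#'
#' @param dataset data.frame in canonical schema.
#' @param max_iter Maximum sweeps over the incomplete columns.
#' @param tol Convergence threshold on the max standardized cell change.
#' @param seed Integer seed (the fit is deterministic given the seed).
#' @param nrounds,max_depth Boosting rounds and tree depth per column model.
#' @return The dataset with all numeric inputs complete.
#' @export
iterative_impute <- function(dataset, max_iter = 10L, tol = 1e-3,
                             seed = 1L, nrounds = 60L, max_depth = 4L) {
  num <- intersect(schema_columns("numeric_input"), names(dataset))
  n_missing <- vapply(dataset[num], function(v) sum(is.na(v)), 0L)
  full_miss <- names(n_missing)[n_missing == nrow(dataset)]
  if (length(full_miss))
    stop("column(s) entirely missing, nothing to learn from: ",
         paste(full_miss, collapse = ", "))
  targets <- names(sort(n_missing[n_missing > 0L]))
  if (!length(targets)) return(dataset)

  masks <- lapply(dataset[targets], is.na)
  scales <- vapply(targets, function(col) {
    s <- sd(dataset[[col]], na.rm = TRUE)
    if (!is.finite(s) || s == 0) 1 else s
  }, 0)
  # median initialization
  for (col in targets) {
    m <- median(dataset[[col]], na.rm = TRUE)
    dataset[[col]][masks[[col]]] <- m
  }
  set.seed(seed)
  for (iter in seq_len(max_iter)) {
    max_delta <- 0
    for (col in targets) {
      mask <- masks[[col]]
      X <- impute_design(dataset, exclude = col)
      obs <- which(!mask)
      fit <- xgboost::xgboost(
        x = X[obs, , drop = FALSE], y = dataset[[col]][obs],
        nrounds = nrounds, max_depth = max_depth, learning_rate = 0.3,
        objective = "reg:squarederror", verbosity = 0, nthreads = 1L)
      pred <- predict(fit, X[mask, , drop = FALSE])
      delta <- max(abs(pred - dataset[[col]][mask]) / scales[[col]], 0)
      dataset[[col]][mask] <- pred
      max_delta <- max(max_delta, delta)
    }
    if (max_delta <= tol) break
  }
  dataset
}

#' Reduce the table to the final modeling feature set
#'
#' Drops redundant and non-causal columns -- organ (encapsulated by the
#' cell line), multiwell (encapsulated by the assay), cell type, the Na 1s
#' and N 1s atomic concentrations (zero-heavy, synthesis-related), the
#' constant 24 h duration, the pretreatment label and the ERM identifier --
#' leaving the 15 modeling inputs plus the viability outcome.
#'
#' @param dataset data.frame in canonical schema (imputed).
#' @return data.frame with 16 columns.
#' @export
finalize_features <- function(dataset) {
  drop <- c("organ", "multiwell", "cell_type", "na1s_at", "n1s_at",
            "duration", "erm_id", "pretreatment")
  dataset[, setdiff(names(dataset), drop), drop = FALSE]
}

#' Final modeling input columns
#' @return Character vector of the 15 modeling inputs.
#' @export
final_feature_columns <- function() {
  c("o1s_at", "ag3d_at", "c1s_at", "core_size", "spherical_surface_area",
    "crystallinity", "avg_crystallite_size", "coating",
    "hydro_size_t0", "hydro_size_t24", "pdi_t0", "pdi_t24",
    "cell_line", "dose", "assay")
}

#' One-hot encode categorical columns
#'
#' Each k-state column becomes k 0/1 indicator columns named
#' `column=state`, in sorted state order; exactly one indicator is 1 per
#' row.  When `levels` (a named list of state sets, e.g. recorded from a
#' training table) is supplied, a state outside the known set raises an
#' error naming it.
#'
#' @param dataset data.frame.
#' @param columns Categorical columns to encode (default: all categorical
#'   schema columns present).
#' @param levels Optional named list of per-column state sets.
#' @return data.frame with indicators replacing the listed columns; the
#'   state sets used are attached as attribute `"one_hot_levels"`.
#' @export
one_hot <- function(dataset,
                    columns = intersect(schema_columns("categorical_input"),
                                        names(dataset)),
                    levels = NULL) {
  used <- list()
  for (col in columns) {
    vals <- as.character(dataset[[col]])
    states <- if (!is.null(levels) && !is.null(levels[[col]]))
      sort(levels[[col]]) else sort(unique(vals))
    unseen <- setdiff(unique(vals), states)
    if (length(unseen))
      stop("unseen state(s) in column '", col, "': ",
           paste(unseen, collapse = ", "))
    for (s in states)
      dataset[[paste0(col, "=", s)]] <- as.numeric(vals == s)
    dataset[[col]] <- NULL
    used[[col]] <- states
  }
  attr(dataset, "one_hot_levels") <- used
  dataset
}

#' Recover a categorical column from its one-hot indicators
#'
#' @param dataset data.frame holding `column=state` indicators.
#' @param column Original column name.
#' @return Character vector of states (argmax over the indicators).
#' @export
one_hot_decode <- function(dataset, column) {
  cols <- grep(paste0("^", column, "="), names(dataset), value = TRUE)
  if (!length(cols)) stop("no indicators found for column '", column, "'")
  states <- sub(paste0("^", column, "="), "", cols)
  idx <- max.col(as.matrix(dataset[, cols, drop = FALSE]),
                 ties.method = "first")
  states[idx]
}

#' SMOTE oversampling of minority hazard classes
#'
#' Synthetic-minority oversampling: for each minority class, new rows are
#' drawn as `x_new = x + u * (x_nn - x)` with `u ~ Uniform(0, 1)` and
#' `x_nn` one of the `k` same-class nearest neighbours (Euclidean distance
#' on z-scored features), until every class matches the majority count.
#' Original rows are preserved verbatim and come first in the output.
#'
#' @param features Fully numeric matrix or data.frame (training rows only).
#' @param labels Factor or character vector of class labels per row.
#' @param k Neighbour count (capped at class size - 1).
#' @param seed Integer seed.
#' @return List with elements `features` (matrix) and `labels` (factor with
#'   the input's level order).
#' @export
smote_oversample <- function(features, labels, k = 5L, seed = 1L) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  lev <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
  labels <- factor(labels, levels = lev)
  counts <- table(labels)
  counts <- counts[counts > 0L]
  if (any(counts == 1L))
    stop("class(es) with a single member cannot be oversampled: ",
         paste(names(counts)[counts == 1L], collapse = ", "))
  target <- max(counts)
  mu <- colMeans(X)
  s <- apply(X, 2, sd); s[s == 0 | !is.finite(s)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, s, "/")
  set.seed(seed)
  new_X <- list(); new_y <- list()
  for (cls in names(counts)) {
    need <- target - counts[[cls]]
    if (need == 0L) next
    idx <- which(labels == cls)
    Zc <- Z[idx, , drop = FALSE]
    D <- as.matrix(dist(Zc))
    diag(D) <- Inf
    kc <- min(k, length(idx) - 1L)
    nn <- matrix(apply(D, 1, function(r) order(r)[seq_len(kc)]),
                 ncol = kc, byrow = TRUE)
    parents <- sample(seq_along(idx), need, replace = TRUE)
    picks <- nn[cbind(parents,
                      sample.int(kc, need, replace = TRUE))]
    u <- runif(need)
    Xp <- X[idx[parents], , drop = FALSE]
    Xn <- X[idx[picks], , drop = FALSE]
    new_X[[cls]] <- Xp + u * (Xn - Xp)
    new_y[[cls]] <- rep(cls, need)
  }
  out_X <- rbind(X, do.call(rbind, new_X))
  out_y <- factor(c(as.character(labels), unlist(new_y)), levels = lev)
  rownames(out_X) <- NULL
  list(features = out_X, labels = out_y)
}

# ---------------------------------------------------------------------------
# Quantile discretization
# ---------------------------------------------------------------------------

#' Fit tercile quantile bins on numeric features
#'
#' Per column, bin edges are placed at the 33.33rd and 66.67th percentiles
#' (linear interpolation between order statistics), splitting the fitting
#' data into three roughly equal-sized bins labelled low / medium / high.
#' Realized numeric edges are stored alongside the percentile ranks so the
#' applicability domain can be reported as ranges.
#'
#' @param dataset data.frame.
#' @param q Number of bins (3).
#' @param columns Numeric columns to bin (default: numeric inputs present).
#' @return Object of class `discretization_map`: named list with `edges`,
#'   `range`, `labels`, `probs` per feature.
#' @export
fit_quantile_bins <- function(dataset, q = 3L,
                              columns = intersect(
                                schema_columns("numeric_input"),
                                names(dataset))) {
  stopifnot(q == 3L)
  map <- list()
  for (col in columns) {
    v <- dataset[[col]]
    v <- v[!is.na(v)]
    if (length(unique(v)) < q)
      stop("degenerate column '", col, "': fewer than ", q,
           " distinct values")
    probs <- c(1, 2) / 3
    edges <- unname(quantile(v, probs = probs, type = 7))
    map[[col]] <- list(edges = edges,
                       range = c(min(v), max(v)),
                       labels = c("low", "medium", "high"),
                       probs = probs)
  }
  structure(map, class = "discretization_map")
}

#' Bin labels for numeric values under a fitted map
#'
#' Left-closed / right-open convention with the high bin open-ended:
#' low = [-Inf, e1), medium = [e1, e2), high = [e2, Inf); values below the
#' fitted minimum fall in `low`.
#'
#' @param x Numeric vector.
#' @param spec One feature's entry of a `discretization_map`.
#' @return Factor with levels low < medium < high.
#' @export
bin_values <- function(x, spec) {
  lab <- ifelse(x < spec$edges[[1L]], "low",
                ifelse(x < spec$edges[[2L]], "medium", "high"))
  factor(lab, levels = spec$labels)
}

#' Apply a discretization map to a dataset
#'
#' Replaces every mapped numeric input by its bin label, turns categorical
#' inputs into factors over their observed states, and discretizes the
#' viability outcome into the three hazard classes.  The result is the
#' all-discrete table used for Bayesian-network training.
#'
#' @param dataset data.frame (complete on the mapped columns).
#' @param map A [fit_quantile_bins()] result.
#' @return data.frame of factors (a binned dataset).
#' @export
apply_bins <- function(dataset, map) {
  out <- dataset
  for (col in names(map)) {
    if (!col %in% names(out)) next
    if (any(is.na(out[[col]])))
      stop("column '", col, "' still has missing values; impute first")
    out[[col]] <- bin_values(out[[col]], map[[col]])
  }
  for (col in intersect(schema_columns("categorical_input"), names(out)))
    out[[col]] <- factor(out[[col]])
  if ("viability" %in% names(out))
    out$viability <- classify_viability(out$viability)
  out
}

#' Serialize a discretization map to JSON
#' @param map A `discretization_map`.
#' @param path Optional output path.
#' @return JSON text (invisibly when written to a file).
#' @export
map_to_json <- function(map, path = NULL) {
  txt <- jsonlite::toJSON(unclass(map), pretty = TRUE, digits = NA,
                          auto_unbox = FALSE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
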