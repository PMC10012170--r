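# ---------------------------------------------------------------------------
# End-to-end pipeline: simulate/load -> preprocess -> explore -> baselines
# -> Bayesian network -> rules -> validate -> report
# ---------------------------------------------------------------------------

#' Antecedent preset for compact worked hazard criteria
#'
#' The worked hazard criteria condition on crystallinity, core size,
#' spherical surface area, Ag 3d atomic concentration, hydrodynamic size
#' at t24, exposure dose, assay and cell line.
#'
#' @return Character vector of feature names.
#' @export
rule_preset_features <- function() {
  c("crystallinity", "core_size", "spherical_surface_area", "ag3d_at",
    "hydro_size_t24", "dose", "assay", "cell_line")
}

#' Pipeline run configuration
#'
#' @param input `"synthetic"` or a path to a CSV/TSV/XLSX experiment table.
#' @param generator [generator_config()] used when `input = "synthetic"`.
#' @param seeds Named integer seeds for every stochastic stage: `split`,
#'   `smote`, `impute`, `models`.
#' @param train_fraction Training fraction of the split.
#' @param smote_mode `"train"` (balance the training split only, the
#'   default) or `"all"` (balance before splitting; reproduces the pooled
#'   row count sometimes quoted for the balanced table).
#' @param score,ess Structure score and equivalent sample size.
#' @param pseudocount CPT smoothing mass.
#' @param max_parents Hill-climbing parent cap.
#' @param rule_features `"markov_blanket"`, `"preset"` (the worked-example
#'   antecedent set) or a character vector of features.
#' @param top_k Rules kept per class after filtering.
#' @param out_dir Output directory for stage artifacts (`NULL` for none).
#' @return Object of class `run_config`.
#' @export
run_config <- function(input = "synthetic",
                       generator = generator_config(),
                       seeds = c(split = 7L, smote = 11L, impute = 13L,
                                 models = 17L),
                       train_fraction = 0.8,
                       smote_mode = c("train", "all"),
                       score = "bdeu", ess = 1,
                       pseudocount = 0.5,
                       max_parents = 6L,
                       rule_features = "markov_blanket",
                       top_k = 5L,
                       out_dir = NULL) {
  smote_mode <- match.arg(smote_mode)
  needed <- c("split", "smote", "impute", "models")
  if (!all(needed %in% names(seeds)))
    stop("config error: seeds must name ",
         paste(needed, collapse = ", "))
  structure(list(input = input, generator = generator, seeds = seeds,
                 train_fraction = train_fraction, smote_mode = smote_mode,
                 score = score, ess = ess, pseudocount = pseudocount,
                 max_parents = max_parents, rule_features = rule_features,
                 top_k = top_k, out_dir = out_dir),
            class = "run_config")
}

#' Balance and discretize a train/test pair for network training
#'
#' One-hot encodes the categorical inputs, applies SMOTE to the training
#' rows (labels = discretized viability), decodes the categoricals back to
#' single multi-state columns, fits tercile bins on the balanced training
#' numerics, and bins both splits.  Class balancing never touches the test
#' rows.
#'
#' @param train,test Finalized (15-feature + viability) data.frames.
#' @param k SMOTE neighbour count.
#' @param seed SMOTE seed.
#' @return List with `train` and `test` (binned data.frames, outcome as
#'   hazard class), `map` (the discretization map) and `class_counts`
#'   (before/after balancing).
#' @export
balance_and_bin <- function(train, test, k = 5L, seed = 1L) {
  cat_cols <- intersect(schema_columns("categorical_input"), names(train))
  num_cols <- intersect(schema_columns("numeric_input"), names(train))
  labels <- classify_viability(train$viability)
  enc <- one_hot(train[, c(num_cols, cat_cols), drop = FALSE],
                 columns = cat_cols)
  levels_used <- attr(enc, "one_hot_levels")
  before <- table(labels)
  bal <- smote_oversample(as.matrix(enc), labels, k = k, seed = seed)
  dec <- as.data.frame(bal$features)
  out_train <- dec[, num_cols, drop = FALSE]
  for (col in cat_cols)
    out_train[[col]] <- one_hot_decode(dec, col)
  map <- fit_quantile_bins(out_train, columns = num_cols)
  binned_train <- apply_bins(out_train, map)
  binned_train$viability <- factor(as.character(bal$labels),
                                   levels = hazard_classes())
  binned_test <- apply_bins(
    test[, c(num_cols, cat_cols, "viability"), drop = FALSE], map)
  # align categorical state sets across splits
  for (col in cat_cols) {
    st <- levels_used[[col]]
    binned_train[[col]] <- factor(as.character(binned_train[[col]]), st)
    binned_test[[col]] <- factor(as.character(binned_test[[col]]), st)
  }
  cols <- c(num_cols, cat_cols, "viability")
  list(train = binned_train[, cols], test = binned_test[, cols],
       map = map, class_counts = list(before = before,
                                      after = table(bal$labels)))
}

#' Learn, fit and validate constrained vs unconstrained structures
#'
#' Learns both structures on the same binned training data, fits CPTs with
#' the same pseudocount, and evaluates both as classifiers on the identical
#' test rows.
#'
#' @param train,test Binned data.frames (outcome = hazard class factor).
#' @param constraints [constraint_set()] for the constrained variant.
#' @param learner `"hillclimb"` or `"exact"`.
#' @param score,ess,max_parents,pseudocount Passed to the learners/fitter.
#' @return List of class `structure_comparison` with `constrained` and
#'   `unconstrained` blocks (structure, bn, training score, test metrics).
#' @export
compare_structures <- function(train, test, constraints,
                               learner = c("hillclimb", "exact"),
                               score = "bdeu", ess = 1, max_parents = 6L,
                               pseudocount = 0.5) {
  learner <- match.arg(learner)
  learn <- function(cs) {
    if (learner == "hillclimb")
      learn_structure_hillclimb(train, score = score, ess = ess,
                                constraints = cs,
                                max_parents = max_parents)
    else
      learn_structure_exact(train, score = score, ess = ess,
                            constraints = cs, max_parents = max_parents)
  }
  evaluate <- function(cs) {
    st <- learn(cs)
    bn <- fit_cpts(st, train, pseudocount = pseudocount)
    pred <- predict_dataset(bn, test)
    list(structure = st, bn = bn,
         train_score = attr(st, "score"),
         metrics = classification_metrics(test$viability, pred))
  }
  structure(list(constrained = evaluate(constraints),
                 unconstrained = evaluate(NULL),
                 n_test = nrow(test)),
            class = "structure_comparison")
}

stage_artifact <- function(out_dir, name, writer) {
  if (is.null(out_dir)) return(NULL)
  path <- file.path(out_dir, name)
  writer(path)
  name
}

#' Run the full pipeline
#'
#' Executes simulate/load, dose interpolation, chained imputation, feature
#' finalization, association analysis, the train/test split, the baseline
#' model sweep, SMOTE balancing and tercile binning, constrained and
#' unconstrained network learning with CPT fitting and external
#' validation, and rule extraction; persists every intermediate artifact
#' to `config$out_dir` (when set) together with a manifest carrying the
#' package version, a config hash and all seeds.  Re-running with the same
#' config reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @return List with the dataset, splits, discretization map, comparison
#'   of structures, rules, baseline reports and the manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  artifacts <- list(); log <- list()
  tick <- function(stage, nrows, t0) {
    log[[stage]] <<- list(rows = nrows,
                          elapsed = round(as.numeric(
                            proc.time()[["elapsed"]] - t0), 3))
  }

  t0 <- proc.time()[["elapsed"]]
  dataset <- if (identical(config$input, "synthetic"))
    generate_dataset(config$generator) else read_dataset(config$input)
  artifacts$dataset <- stage_artifact(out_dir, "01_dataset.csv",
    function(p) write_dataset(dataset, p))
  tick("simulate", nrow(dataset), t0)

  t0 <- proc.time()[["elapsed"]]
  imputed <- interpolate_strata(dataset)
  imputed <- iterative_impute(imputed, seed = config$seeds[["impute"]])
  final <- finalize_features(imputed)
  artifacts$imputed <- stage_artifact(out_dir, "02_imputed.csv",
    function(p) write_dataset(imputed, p))
  tick("preprocess", nrow(final), t0)

  t0 <- proc.time()[["elapsed"]]
  assoc <- association_matrix(final)
  skew <- vapply(final[vapply(final, is.numeric, NA)], skewness, 0)
  artifacts$associations <- stage_artifact(out_dir, "03_associations.csv",
    function(p) write.csv(assoc$matrix, p))
  tick("eda", nrow(final), t0)

  t0 <- proc.time()[["elapsed"]]
  split <- split_dataset(final, fraction = config$train_fraction,
                         stratify = TRUE, seed = config$seeds[["split"]])
  tick("split", nrow(split$train), t0)

  t0 <- proc.time()[["elapsed"]]
  cat_cols <- intersect(schema_columns("categorical_input"), names(final))
  enc_train <- one_hot(split$train, columns = cat_cols)
  enc_test <- one_hot(split$test, columns = cat_cols,
                      levels = attr(enc_train, "one_hot_levels"))
  reg <- fit_regressors(enc_train, enc_test,
                        seed = config$seeds[["models"]])
  cls_train <- enc_train
  cls_train$viability <- NULL
  bal <- smote_oversample(as.matrix(cls_train),
                          classify_viability(split$train$viability),
                          seed = config$seeds[["smote"]])
  cls_train_df <- as.data.frame(bal$features)
  cls_train_df$viability <- bal$labels
  cls_test_df <- enc_test
  cls_test_df$viability <- classify_viability(split$test$viability)
  cls <- fit_classifiers(cls_train_df, cls_test_df,
                         seed = config$seeds[["models"]])
  lb_reg <- cbind(task = "regression", leaderboard(reg))
  lb_cls <- cbind(task = "classification", leaderboard(cls))
  all_cols <- union(names(lb_reg), names(lb_cls))
  for (col in setdiff(all_cols, names(lb_reg))) lb_reg[[col]] <- NA
  for (col in setdiff(all_cols, names(lb_cls))) lb_cls[[col]] <- NA
  lb <- rbind(lb_reg[all_cols], lb_cls[all_cols])
  artifacts$leaderboard <- stage_artifact(out_dir, "04_leaderboard.csv",
    function(p) write.csv(lb, p, row.names = FALSE))
  tick("baselines", nrow(cls_train_df), t0)

  t0 <- proc.time()[["elapsed"]]
  bb <- balance_and_bin(split$train, split$test,
                        seed = config$seeds[["smote"]])
  artifacts$binned <- stage_artifact(out_dir, "05_binned_train.csv",
    function(p) write.csv(bb$train, p, row.names = FALSE))
  artifacts$map <- stage_artifact(out_dir, "05_discretization_map.json",
    function(p) map_to_json(bb$map, p))
  tick("discretize", nrow(bb$train), t0)

  t0 <- proc.time()[["elapsed"]]
  constraints <- asina_constraints(names(bb$train))
  comparison <- compare_structures(bb$train, bb$test, constraints,
                                   learner = "hillclimb",
                                   score = config$score, ess = config$ess,
                                   max_parents = config$max_parents,
                                   pseudocount = config$pseudocount)
  artifacts$structure <- stage_artifact(out_dir, "06_structure.graphml",
    function(p) write_structure(comparison$constrained$structure, p))
  artifacts$cpts <- stage_artifact(out_dir, "06_cpts.json",
    function(p) cpts_to_json(comparison$constrained$bn, p))
  tick("bayes_net", nrow(bb$train), t0)

  t0 <- proc.time()[["elapsed"]]
  features <- switch(paste(config$rule_features[[1L]]),
    markov_blanket = markov_blanket(comparison$constrained$bn,
                                    "viability"),
    preset = intersect(rule_preset_features(), names(bb$train)),
    config$rule_features)
  rules <- enumerate_rules(comparison$constrained$bn,
                           evidence_features = features, data = bb$train)
  merged <- if ("dose" %in% features) merge_over(rules, "dose") else rules
  top <- do.call(c, lapply(hazard_classes(), function(cl)
    filter_rules(merged, class = cl, top_k = config$top_k)))
  artifacts$rules <- stage_artifact(out_dir, "07_rules.json",
    function(p) write_rules(rules, json_path = p, map = bb$map))
  artifacts$top_rules <- stage_artifact(out_dir, "07_top_rules.csv",
    function(p) write.csv(rules_to_df(top), p, row.names = FALSE))
  tick("rules", length(rules), t0)

  manifest <- list(
    package_version = as.character(utils::packageVersion("hazardbn")),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    seeds = as.list(config$seeds),
    generator_seed = if (identical(config$input, "synthetic"))
      config$generator$seed else NULL,
    stages = log,
    artifacts = artifacts)
  if (!is.null(out_dir))
    writeLines(jsonlite::toJSON(manifest, pretty = TRUE,
                                auto_unbox = TRUE),
               file.path(out_dir, "manifest.json"))
  list(dataset = dataset, imputed = imputed, final = final,
       associations = assoc, skewness = skew, split = split,
       regressors = reg, classifiers = cls, binned = bb,
       comparison = comparison, rules = rules, top_rules = top,
       manifest = manifest)
}
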