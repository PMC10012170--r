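# ---------------------------------------------------------------------------
# IF-THEN hazard rules mined from CPTs, with certainty factors
# ---------------------------------------------------------------------------

#' Certainty factor of a rule
#'
#' Odds for versus against the consequent given the antecedent:
#' `cf = p / (1 - p)` (posterior odds).  `p = 1` yields `Inf`, which the
#' rule extractor discards (a class with no counterexamples carries no
#' finite odds).  Supplying a `prior` switches to the likelihood-ratio
#' variant `cf = [p / (1 - p)] / [prior / (1 - prior)]`, the posterior-odds
#' update factor contributed by the evidence alone.
#'
#' @param p Posterior probability of the consequent in [0, 1].
#' @param prior Optional prior probability of the consequent.
#' @return Certainty factor (>= 0, possibly `Inf`).
#' @export
certainty_factor <- function(p, prior = NULL) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  cf <- ifelse(p == 1, Inf, p / (1 - p))
  if (!is.null(prior)) {
    if (any(prior <= 0 | prior >= 1)) stop("prior must be in (0, 1)")
    cf <- cf / (prior / (1 - prior))
  }
  cf
}

new_rule <- function(antecedent, consequent, probability, cf,
                     n_configs = 1L, support = NA_integer_,
                     merged = character()) {
  structure(list(antecedent = antecedent, consequent = consequent,
                 probability = probability, cf = cf,
                 n_configs = n_configs, support = support,
                 merged = merged),
            class = "hazard_rule")
}

#' Mine hazard rules from a trained network
#'
#' For every joint configuration of the evidence features with nonzero
#' probability under the network, the exact posterior of the outcome is
#' computed and one rule per (configuration, class) is emitted, carrying
#' that class's posterior probability and its certainty factor.  Rules
#' with infinite certainty factor (posterior exactly 1) are discarded;
#' zero-probability configurations are skipped before emission.  Both
#' counts are recorded as attributes `"n_discarded_infinite"` and
#' `"n_zero_configs"`.
#'
#' @param bn A `bayes_net`.
#' @param target Outcome node.
#' @param evidence_features Antecedent features (default: the target's
#'   Markov blanket in the trained structure).
#' @param data Optional training data used to attach per-rule support
#'   counts (rows matching the antecedent).
#' @param min_prob Configurations with joint probability below this are
#'   treated as zero (guards floating-point dust).
#' @return List of `hazard_rule` objects.
#' @export
enumerate_rules <- function(bn, target = "viability",
                            evidence_features = markov_blanket(bn, target),
                            data = NULL, min_prob = 1e-12) {
  if (!length(evidence_features))
    stop("evidence_features must be non-empty")
  missing_f <- setdiff(c(evidence_features, target), bn$nodes)
  if (length(missing_f))
    stop("feature(s) not in the network: ",
         paste(missing_f, collapse = ", "))
  evidence_features <- sort(evidence_features)
  joint <- joint_marginal(bn, c(evidence_features, target))
  states <- bn$states[evidence_features]
  grid <- do.call(expand.grid, c(states, list(stringsAsFactors = FALSE,
                                              KEEP.OUT.ATTRS = FALSE)))
  classes <- bn$states[[target]]
  rules <- list()
  n_zero <- 0L; n_inf <- 0L
  support_key <- NULL
  if (!is.null(data)) {
    support_key <- do.call(paste, c(lapply(data[evidence_features],
                                           as.character), sep = "\r"))
  }
  for (i in seq_len(nrow(grid))) {
    cfg <- as.character(grid[i, , drop = TRUE])
    names(cfg) <- evidence_features
    p_joint <- vapply(classes, function(cl)
      joint[matrix(c(cfg, cl), nrow = 1)], 0)
    z <- sum(p_joint)
    if (z <= min_prob) { n_zero <- n_zero + 1L; next }
    supp <- if (is.null(support_key)) NA_integer_ else
      sum(support_key == paste(cfg, collapse = "\r"))
    for (cl in classes) {
      p <- p_joint[[cl]] / z
      cf <- certainty_factor(min(p, 1))
      if (!is.finite(cf)) { n_inf <- n_inf + 1L; next }
      rules[[length(rules) + 1L]] <-
        new_rule(cfg, cl, p, cf, n_configs = 1L, support = supp)
    }
  }
  attr(rules, "n_zero_configs") <- n_zero
  attr(rules, "n_discarded_infinite") <- n_inf
  rules
}

antecedent_key <- function(rule, drop = character()) {
  a <- rule$antecedent[setdiff(names(rule$antecedent), drop)]
  a <- a[order(names(a))]
  paste(names(a), a, sep = "=", collapse = "^")
}

#' Merge rules over one free feature
#'
#' Groups rules that are identical except for the bin of `free_feature`
#' (and share a consequent), removes that condition, and pools the members:
#' probability and certainty factor become arithmetic means, configuration
#' counts and supports are summed.  This is how a per-dose-bin family of
#' rules collapses into a single "under any exposure range" rule whose
#' mean-of-odds certainty factor can far exceed the odds of its mean
#' probability.
#'
#' @param rules List of `hazard_rule`.
#' @param free_feature Feature whose condition is pooled away.
#' @return List of merged `hazard_rule` objects.
#' @export
merge_over <- function(rules, free_feature) {
  if (!length(rules)) return(rules)
  keys <- vapply(rules, function(r)
    paste(r$consequent, antecedent_key(r, drop = free_feature),
          sep = "\r"), "")
  out <- list()
  for (k in unique(keys)) {
    members <- rules[keys == k]
    cons <- unique(vapply(members, `[[`, "", "consequent"))
    if (length(cons) > 1L)
      stop("inconsistent consequents within a merge group")
    a <- members[[1L]]$antecedent
    a <- a[setdiff(names(a), free_feature)]
    supports <- vapply(members, `[[`, NA_integer_, "support")
    out[[length(out) + 1L]] <- new_rule(
      antecedent = a, consequent = cons,
      probability = mean(vapply(members, `[[`, 0, "probability")),
      cf = mean(vapply(members, `[[`, 0, "cf")),
      n_configs = sum(vapply(members, `[[`, 0L, "n_configs")),
      support = if (all(is.na(supports))) NA_integer_
                else sum(supports, na.rm = TRUE),
      merged = sort(unique(c(members[[1L]]$merged, free_feature))))
  }
  out
}

#' Filter rules by class and rank by certainty factor
#'
#' Keeps rules of the requested hazard class, sorted by certainty factor
#' descending (ties broken by support descending, then lexicographically by
#' antecedent), truncated to the top `k`.
#'
#' @param rules List of `hazard_rule`.
#' @param class Hazard class to keep (`NULL` keeps all).
#' @param top_k Maximum number of rules returned.
#' @return List of `hazard_rule`.
#' @export
filter_rules <- function(rules, class = NULL, top_k = Inf) {
  if (!is.null(class))
    rules <- rules[vapply(rules, `[[`, "", "consequent") == class]
  if (!length(rules)) return(rules)
  cf <- vapply(rules, `[[`, 0, "cf")
  supp <- vapply(rules, `[[`, NA_integer_, "support")
  supp[is.na(supp)] <- -1L
  key <- vapply(rules, antecedent_key, "")
  rules <- rules[order(-cf, -supp, key)]
  rules[seq_len(min(top_k, length(rules)))]
}

#' Display names used in formatted rules
#' @return Named character vector mapping schema columns to print names.
#' @export
feature_display_names <- function() {
  c(o1s_at = "O 1s at. %", ag3d_at = "Ag 3d at. %", c1s_at = "C 1s at. %",
    core_size = "core size", spherical_surface_area =
      "spherical surface area", crystallinity = "crystallinity",
    avg_crystallite_size = "av crystallite sizes",
    hydro_size_t0 = "hydrodynamic size t0",
    hydro_size_t24 = "hydrodynamic size t24",
    pdi_t0 = "pol index t0", pdi_t24 = "pol index t24",
    dose = "exposure dose", coating = "coating",
    cell_line = "cell line", assay = "assay")
}

fmt_num <- function(x) formatC(signif(x, 6), format = "fg", big.mark = "")

bin_condition_text <- function(label, spec) {
  switch(label,
    low = sprintf("L(%s → %s)", fmt_num(spec$range[[1L]]),
                  fmt_num(spec$edges[[1L]])),
    medium = sprintf("M(%s → %s)", fmt_num(spec$edges[[1L]]),
                     fmt_num(spec$edges[[2L]])),
    high = sprintf("H(>%s)", fmt_num(spec$edges[[2L]])))
}

#' Format a rule in IF/THEN notation
#'
#' Renders the antecedent as a `^`-joined conjunction with bins shown as
#' L/M/H plus their realized numeric ranges, the consequent as
#' `THEN AgNFs are <class>`, the dose condition as an
#' `if tested under <bin> (<range>) dose` clause (or
#' `under any exposure range` when the dose was merged away), and appends
#' the probability and certainty factor.
#'
#' @param rule A `hazard_rule`.
#' @param map [fit_quantile_bins()] map supplying numeric ranges.
#' @return Single-line character string.
#' @export
format_rule <- function(rule, map) {
  disp <- feature_display_names()
  conds <- character()
  dose_clause <- ""
  for (f in names(rule$antecedent)) {
    val <- rule$antecedent[[f]]
    name <- if (f %in% names(disp)) disp[[f]] else f
    txt <- if (!is.null(map[[f]]) && val %in% c("low", "medium", "high"))
      bin_condition_text(val, map[[f]]) else val
    if (f == "dose") {
      rng <- switch(val,
        low = sprintf("(%s → %s)", fmt_num(map$dose$range[[1L]]),
                      fmt_num(map$dose$edges[[1L]])),
        medium = sprintf("(%s → %s)", fmt_num(map$dose$edges[[1L]]),
                         fmt_num(map$dose$edges[[2L]])),
        high = sprintf("(≥%s)", fmt_num(map$dose$edges[[2L]])))
      dose_clause <- sprintf(" if tested under %s %s dose", val, rng)
    } else {
      conds <- c(conds, sprintf("(%s) = %s", name, txt))
    }
  }
  if ("dose" %in% rule$merged)
    dose_clause <- " if tested under any exposure range"
  lhs <- if (length(conds)) paste0("IF ", paste(conds, collapse = "^"), " ")
         else "IF (any conditions) "
  avg <- if (rule$n_configs > 1L) "an average " else "a "
  sprintf("%sTHEN AgNFs are %s%s with %s%.2f probability (CF = %.1f)",
          lhs, gsub("_", " ", rule$consequent), dose_clause, avg,
          rule$probability, rule$cf)
}

#' Parse a formatted rule back into a `hazard_rule`
#'
#' Inverse of [format_rule()] up to the printed rounding of probability and
#' certainty factor.
#'
#' @param text One formatted rule line.
#' @return A `hazard_rule`.
#' @export
parse_rule <- function(text) {
  disp <- feature_display_names()
  inv <- setNames(names(disp), disp)
  antecedent <- character()
  merged <- character()
  lhs <- sub("^IF ", "", sub(" THEN .*$", "", text))
  if (lhs != "(any conditions)") {
    for (part in strsplit(lhs, "^", fixed = TRUE)[[1L]]) {
      m <- regmatches(part, regexec("^\\((.+)\\) = (.+)$", part))[[1L]]
      f <- trimws(m[[2L]]); val <- trimws(m[[3L]])
      f <- if (f %in% names(inv)) inv[[f]] else f
      lab <- if (grepl("^L\\(", val)) "low"
             else if (grepl("^M\\(", val)) "medium"
             else if (grepl("^H\\(", val)) "high"
             else val
      antecedent[[f]] <- lab
    }
  }
  cons <- gsub(" ", "_",
    regmatches(text, regexec("THEN AgNFs are ([a-z_ ]+?)( if| with)",
                             text))[[1L]][[2L]])
  if (grepl("under any exposure range", text)) {
    merged <- "dose"
  } else {
    md <- regmatches(text,
      regexec("under (low|medium|high) \\(", text))[[1L]]
    if (length(md)) antecedent[["dose"]] <- md[[2L]]
  }
  p <- as.numeric(regmatches(text,
    regexec("([0-9.]+) probability", text))[[1L]][[2L]])
  cf <- as.numeric(regmatches(text,
    regexec("CF = ([0-9.]+)", text))[[1L]][[2L]])
  n_cfg <- if (grepl("an average", text)) 2L else 1L
  new_rule(antecedent[order(names(antecedent))], cons, p, cf,
           n_configs = n_cfg, merged = merged)
}

#' Summarize rules as a data.frame
#' @param rules List of `hazard_rule`.
#' @return data.frame with one row per rule.
#' @export
rules_to_df <- function(rules) {
  if (!length(rules))
    return(data.frame(antecedent = character(), class = character(),
                      probability = numeric(), cf = numeric(),
                      n_configs = integer(), support = integer()))
  data.frame(
    antecedent = vapply(rules, antecedent_key, ""),
    class = vapply(rules, `[[`, "", "consequent"),
    probability = vapply(rules, `[[`, 0, "probability"),
    cf = vapply(rules, `[[`, 0, "cf"),
    n_configs = vapply(rules, `[[`, 0L, "n_configs"),
    support = vapply(rules, `[[`, NA_integer_, "support"),
    stringsAsFactors = FALSE)
}

#' Export rules to JSON (structured) or CSV (summary)
#' @param rules List of `hazard_rule`.
#' @param json_path,csv_path Optional output paths.
#' @param map Optional discretization map; when given, a `text` field with
#'   the formatted notation is included in the JSON.
#' @return `rules`, invisibly.
#' @export
write_rules <- function(rules, json_path = NULL, csv_path = NULL,
                        map = NULL) {
  if (!is.null(json_path)) {
    obj <- lapply(rules, function(r) {
      o <- list(antecedent = as.list(r$antecedent),
                consequent = r$consequent,
                probability = r$probability, cf = r$cf,
                n_configs = r$n_configs, support = r$support,
                merged = r$merged)
      if (!is.null(map)) o$text <- format_rule(r, map)
      o
    })
    writeLines(jsonlite::toJSON(obj, pretty = TRUE, digits = NA,
                                auto_unbox = TRUE, na = "null"),
               json_path)
  }
  if (!is.null(csv_path))
    write.csv(rules_to_df(rules), csv_path, row.names = FALSE)
  invisible(rules)
}
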