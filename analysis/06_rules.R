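#!/usr/bin/env Rscript
# Stage 6: mine the constrained network's conditional probability tables
# into IF-THEN hazard criteria with certainty factors, pool the dose
# condition, and keep the highest-confidence rules per hazard class.

suppressMessages(library(hazardbn))

final <- read.csv("results/02_final_features.csv", stringsAsFactors = FALSE)
sp <- split_dataset(final, fraction = 0.8, stratify = TRUE, seed = 7L)
bb <- balance_and_bin(sp$train, sp$test, seed = 11L)
cs <- asina_constraints(names(bb$train))
st <- learn_structure_hillclimb(bb$train, constraints = cs,
                                max_parents = 6L)
bn <- fit_cpts(st, bb$train, pseudocount = 0.5)

rules <- enumerate_rules(bn, target = "viability", data = bb$train)
cat(sprintf(
  "extracted %d rules over the outcome's Markov blanket (%s)\n",
  length(rules),
  paste(markov_blanket(bn, "viability"), collapse = ", ")))
cat(sprintf("configurations skipped as impossible: %d; ",
            attr(rules, "n_zero_configs")),
    sprintf("infinite-CF rules discarded: %d\n",
            attr(rules, "n_discarded_infinite")))
write_rules(rules, json_path = "results/06_rules.json",
            csv_path = "results/06_rules.csv", map = bb$map)

merged <- merge_over(rules, "dose")
top <- do.call(c, lapply(hazard_classes(), function(cl)
  filter_rules(merged, class = cl, top_k = 3L)))
txt <- vapply(top, format_rule, "", map = bb$map)
writeLines(txt, "results/06_top_rules.txt")
cat("highest-certainty criteria per class (dose pooled):\n")
cat(paste0("  ", txt, collapse = "\n"), "\n")
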