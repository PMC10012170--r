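test_that("certainty factors are posterior odds with the documented
          behaviour at the boundaries", {
  expect_equal(certainty_factor(0.87), 0.87 / 0.13)
  expect_equal(round(certainty_factor(0.87), 1), 6.7)
  expect_equal(certainty_factor(0.5), 1)
  expect_identical(certainty_factor(1), Inf)
  expect_equal(certainty_factor(0), 0)
  expect_error(certainty_factor(1.2), "0, 1")
  expect_error(certainty_factor(-0.1), "0, 1")
  # strictly increasing on [0, 1) and cf(p) * cf(1-p) = 1
  p <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(certainty_factor(p)) > 0))
  expect_equal(certainty_factor(p) * certainty_factor(1 - p),
               rep(1, length(p)))
  # likelihood-ratio variant divides out the prior odds
  expect_equal(certainty_factor(0.8, prior = 0.5), 4)
  expect_equal(certainty_factor(0.8, prior = 0.8), 1)
})

test_that("rule enumeration emits one rule per configuration and class,
          matching independent posterior recomputation", {
  bn <- toy_outcome_bn()
  rules <- enumerate_rules(bn, target = "viability",
                           evidence_features = "dose")
  # 3 dose bins x 3 classes, no zero configurations, no infinite CFs
  expect_length(rules, 9L)
  expect_equal(attr(rules, "n_zero_configs"), 0L)
  expect_equal(attr(rules, "n_discarded_infinite"), 0L)
  for (r in rules) {
    p_ref <- posterior(bn, list(dose = r$antecedent[["dose"]]),
                       "viability")[[r$consequent]]
    expect_equal(r$probability, p_ref, tolerance = 1e-10)
    expect_equal(r$cf, p_ref / (1 - p_ref), tolerance = 1e-10)
    expect_true(is.finite(r$cf))
  }
  # a single binary parent: 2 configurations x |classes|
  states <- list(x = c("0", "1"), y = c("n", "p"))
  bn2 <- structure(list(
    nodes = c("x", "y"), parents = list(x = character(), y = "x"),
    states = states,
    cpts = list(
      x = array(c(0.5, 0.5), 2, dimnames = list(x = states$x)),
      y = array(c(0.8, 0.2, 0.3, 0.7), c(2, 2),
                dimnames = list(y = states$y, x = states$x))),
    pseudocount = 0), class = "bayes_net")
  expect_length(enumerate_rules(bn2, "y", "x"), 4L)
})

test_that("deterministic posteriors are discarded as infinite-confidence
          rules, not emitted", {
  states <- list(x = c("0", "1"), y = c("n", "p"))
  bn <- structure(list(
    nodes = c("x", "y"), parents = list(x = character(), y = "x"),
    states = states,
    cpts = list(
      x = array(c(0.5, 0.5), 2, dimnames = list(x = states$x)),
      y = array(c(1, 0, 0.3, 0.7), c(2, 2),
                dimnames = list(y = states$y, x = states$x))),
    pseudocount = 0), class = "bayes_net")
  rules <- enumerate_rules(bn, "y", "x")
  # x=0 gives P(y=n)=1 (discarded) and P(y=p)=0 (kept, cf 0)
  expect_equal(attr(rules, "n_discarded_infinite"), 1L)
  expect_length(rules, 3L)
  expect_true(all(is.finite(vapply(rules, `[[`, 0, "cf"))))
})

test_that("merging over a free feature averages probabilities and odds", {
  mk <- function(dose_bin, p) hazardbn:::new_rule(
    c(crystallinity = "high", dose = dose_bin), "safe", p, p / (1 - p))
  merged <- merge_over(list(mk("low", 0.9), mk("medium", 0.9),
                            mk("high", 0.9)), "dose")
  expect_length(merged, 1L)
  expect_equal(merged[[1L]]$probability, 0.9)
  expect_equal(merged[[1L]]$cf, 9)
  expect_false("dose" %in% names(merged[[1L]]$antecedent))
  expect_equal(merged[[1L]]$merged, "dose")
  expect_equal(merged[[1L]]$n_configs, 3L)

  # mean of odds dwarfs odds of the mean: (0.99, 0.90, 0.72)
  m2 <- merge_over(list(mk("low", 0.99), mk("medium", 0.90),
                        mk("high", 0.72)), "dose")
  expect_equal(m2[[1L]]$probability, 0.87)
  expect_equal(m2[[1L]]$cf, mean(c(99, 9, 0.72 / 0.28)),
               tolerance = 1e-12)
  expect_equal(round(m2[[1L]]$cf, 1), 36.9)

  # single-member group: condition dropped, values kept
  m3 <- merge_over(list(mk("low", 0.6)), "dose")
  expect_equal(m3[[1L]]$probability, 0.6)
  expect_false("dose" %in% names(m3[[1L]]$antecedent))

  # groups with distinct consequents never merge together
  r_safe <- mk("low", 0.8)
  r_tox <- hazardbn:::new_rule(c(crystallinity = "high", dose = "low"),
                               "toxic", 0.2, 0.25)
  out <- merge_over(list(r_safe, r_tox), "dose")
  expect_length(out, 2L)
})

test_that("filtering keeps the requested class sorted by certainty
          factor", {
  mk <- function(cls, cf, feat) hazardbn:::new_rule(
    setNames("high", feat), cls, cf / (1 + cf), cf)
  rules <- list(mk("safe", 35, "a"), mk("toxic", 50, "b"),
                mk("safe", 6.7, "c"), mk("safe", 1.2, "d"))
  top <- filter_rules(rules, class = "safe", top_k = 2L)
  expect_length(top, 2L)
  expect_equal(vapply(top, `[[`, 0, "cf"), c(35, 6.7))
  expect_true(all(vapply(top, `[[`, "", "consequent") == "safe"))
  expect_length(filter_rules(list(), class = "safe"), 0L)
})

test_that("formatted rules use the L/M/H IF/THEN notation and parse back", {
  map <- list(
    crystallinity = list(edges = c(60, 61), range = c(22.9, 65),
                         labels = c("low", "medium", "high")),
    core_size = list(edges = c(17.8, 20), range = c(7, 25),
                     labels = c("low", "medium", "high")),
    dose = list(edges = c(20, 58.35), range = c(0, 100),
                labels = c("low", "medium", "high")))
  rule <- hazardbn:::new_rule(
    c(crystallinity = "high", core_size = "medium", dose = "low"),
    "safe", 0.81, 0.81 / 0.19)
  txt <- format_rule(rule, map)
  expect_match(txt, "(crystallinity) = H(>61)", fixed = TRUE)
  expect_match(txt, "(core size) = M(17.8 → 20)", fixed = TRUE)
  expect_match(txt, "THEN AgNFs are safe")
  expect_match(txt, "under low \\(0 → 20\\) dose")
  back <- parse_rule(txt)
  expect_equal(back$antecedent, rule$antecedent[order(names(rule$antecedent))])
  expect_equal(back$consequent, "safe")
  expect_equal(back$probability, 0.81, tolerance = 0.005)
  expect_equal(back$cf, round(rule$cf, 1), tolerance = 0.05)

  # merged dose renders as "any exposure range"
  merged <- merge_over(list(
    hazardbn:::new_rule(c(crystallinity = "high", dose = "low"),
                        "safe", 0.9, 9),
    hazardbn:::new_rule(c(crystallinity = "high", dose = "medium"),
                        "safe", 0.84, 5.25)), "dose")
  txt2 <- format_rule(merged[[1L]], map)
  expect_match(txt2, "under any exposure range")
  expect_match(txt2, "an average")
  back2 <- parse_rule(txt2)
  expect_equal(back2$merged, "dose")
})

test_that("rule tables and exports carry every field", {
  bn <- toy_outcome_bn()
  rules <- enumerate_rules(bn, "viability", "dose")
  df <- rules_to_df(rules)
  expect_equal(nrow(df), 9L)
  expect_setequal(unique(df$class), hazard_classes())
  jpath <- withr::local_tempfile(fileext = ".json")
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_rules(rules, json_path = jpath, csv_path = cpath)
  parsed <- jsonlite::fromJSON(jpath, simplifyVector = FALSE)
  expect_length(parsed, 9L)
  expect_equal(nrow(read.csv(cpath)), 9L)
})
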