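test_that("the expert constraint set encodes the stated arcs and
          prohibitions", {
  cs <- asina_constraints()
  req <- paste(cs$required$from, cs$required$to, sep = "->")
  expect_true("dose->viability" %in% req)
  expect_true("assay->viability" %in% req)
  expect_true("coating->spherical_surface_area" %in% req)
  expect_true("coating->ag3d_at" %in% req)
  forb <- paste(cs$forbidden$from, cs$forbidden$to, sep = "->")
  expect_true("hydro_size_t24->dose" %in% forb)
  expect_true("pdi_t24->pdi_t0" %in% forb)
  expect_true("core_size->coating" %in% forb)
  expect_true("viability->dose" %in% forb)
  expect_setequal(cs$roots, c("dose", "assay"))
  expect_equal(cs$sink, "viability")
  # a required arc may not simultaneously be forbidden
  expect_error(constraint_set(
    required = data.frame(from = "a", to = "b"),
    forbidden = data.frame(from = "a", to = "b")), "required and forbidden")
})

test_that("constraint sets survive a JSON round trip", {
  cs <- asina_constraints()
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    required = cs$required, forbidden = cs$forbidden,
    roots = cs$roots, sink = cs$sink), auto_unbox = TRUE), path)
  back <- read_constraints(path)
  expect_equal(back$required, cs$required, ignore_attr = TRUE)
  expect_setequal(back$roots, cs$roots)
  expect_equal(back$sink, "viability")
})

sim_copy_fixture <- function(n = 500, seed = 21L) {
  set.seed(seed)
  x <- factor(sample(c("a", "b"), n, TRUE))
  z <- factor(sample(c("a", "b"), n, TRUE))
  data.frame(X = x, Y = x, Z = z)
}

test_that("exact search finds the dependent pair and ignores the
          independent variable", {
  d <- sim_copy_fixture()
  st <- learn_structure_exact(d)
  arcs <- structure_arcs(st)
  skel <- paste(pmin(arcs$from, arcs$to), pmax(arcs$from, arcs$to))
  expect_true("X Y" %in% skel)
  expect_false(any(grepl("Z", skel)))
})

test_that("exact search attains the exhaustive-enumeration optimum on
          4-node data", {
  set.seed(22)
  d <- as.data.frame(lapply(1:4, function(i)
    factor(sample(c("u", "v"), 120, TRUE))))
  names(d) <- paste0("v", 1:4)
  d$v2 <- factor(ifelse(runif(120) < 0.8, as.character(d$v1),
                        as.character(d$v2)), levels = c("u", "v"))
  oracle <- exhaustive_best_score(d)
  expect_equal(oracle$n_dags, 543L)
  st <- learn_structure_exact(d)
  expect_equal(attr(st, "score"), oracle$best, tolerance = 1e-12)
})

test_that("hill climbing respects the parent cap, improves monotonically
          and matches the exact optimum on the easy fixture", {
  d <- sim_copy_fixture(seed = 23L)
  st <- learn_structure_hillclimb(d)
  expect_true(all(lengths(st$parents) <= 6L))
  trace <- attr(st, "score_trace")
  expect_true(all(diff(trace) > 0))
  ex <- learn_structure_exact(d)
  expect_equal(attr(st, "score"), attr(ex, "score"), tolerance = 1e-9)
})

test_that("constrained structures carry every required arc, avoid
          forbidden arcs, and score no better than unconstrained", {
  d <- finalize_features(iterative_impute(interpolate_strata(
    generate_dataset(small_generator(seed = 24L)))))
  map <- fit_quantile_bins(d)
  binned <- apply_bins(d, map)
  cs <- asina_constraints(names(binned))
  st <- learn_structure_hillclimb(binned, constraints = cs)
  arcs <- paste(structure_arcs(st)$from, structure_arcs(st)$to,
                sep = "->")
  for (r in seq_len(nrow(cs$required)))
    expect_true(paste(cs$required$from[[r]], cs$required$to[[r]],
                      sep = "->") %in% arcs)
  for (f in seq_len(nrow(cs$forbidden)))
    expect_false(paste(cs$forbidden$from[[f]], cs$forbidden$to[[f]],
                       sep = "->") %in% arcs)
  # roots have no parents; viability is the unique childless node
  expect_length(st$parents$dose, 0L)
  expect_length(st$parents$assay, 0L)
  children <- table(structure_arcs(st)$from)
  expect_false("viability" %in% names(children))
  expect_setequal(setdiff(names(binned), names(children)), "viability")

  # constrained optimum cannot beat the unconstrained optimum (exact DP)
  small <- binned[, c("dose", "assay", "cell_line", "viability")]
  cs_small <- asina_constraints(names(small))
  sc_con <- attr(learn_structure_exact(small, constraints = cs_small),
                 "score")
  sc_unc <- attr(learn_structure_exact(small), "score")
  expect_lte(sc_con, sc_unc + 1e-9)
})

test_that("CPT estimation applies the pseudocount exactly", {
  d <- data.frame(a = factor(c("A", "A", "A", "B"), levels = c("A", "B")))
  st <- learn_structure_exact(d)
  bn <- fit_cpts(st, d, pseudocount = 0.5)
  expect_equal(as.numeric(bn$cpts$a), c(0.7, 0.3))
  # zero data: uniform smoothed rows
  d0 <- d[0, , drop = FALSE]
  bn0 <- fit_cpts(st, d0, pseudocount = 0.5)
  expect_equal(as.numeric(bn0$cpts$a), c(0.5, 0.5))
  # every CPT row of a fitted network sums to 1
  d2 <- sim_copy_fixture(seed = 25L)
  bn2 <- fit_cpts(learn_structure_hillclimb(d2), d2)
  for (v in bn2$nodes) {
    cpt <- bn2$cpts[[v]]
    sums <- if (length(dim(cpt)) == 1L) sum(cpt)
            else apply(cpt, seq_along(dim(cpt))[-1], sum)
    expect_equal(as.numeric(sums), rep(1, length(sums)),
                 tolerance = 1e-12)
  }
})

test_that("posterior inference reproduces Bayes' rule on the two-node
          textbook network", {
  states <- list(A = c("0", "1"), B = c("0", "1"))
  bn <- structure(list(
    nodes = c("A", "B"),
    parents = list(A = character(), B = "A"),
    states = states,
    cpts = list(
      A = array(c(0.5, 0.5), dim = 2, dimnames = list(A = states$A)),
      B = array(c(0.9, 0.1, 0.1, 0.9), dim = c(2, 2),
                dimnames = list(B = states$B, A = states$A))),
    pseudocount = 0), class = "bayes_net")
  p <- posterior(bn, list(B = "1"), "A")
  expect_equal(unname(p[["1"]]), 0.9, tolerance = 1e-12)
  # no evidence: prior marginal
  expect_equal(unname(posterior(bn, list(), "A")), c(0.5, 0.5))
})

test_that("variable elimination agrees with joint enumeration on random
          networks", {
  for (seed in 1:8) {
    bn <- random_bn(n_nodes = sample(3:6, 1), seed = seed)
    set.seed(seed + 100)
    ev_nodes <- sample(bn$nodes, sample(0:2, 1))
    target <- sample(setdiff(bn$nodes, ev_nodes), 1)
    evidence <- lapply(ev_nodes, function(v) sample(bn$states[[v]], 1))
    names(evidence) <- ev_nodes
    expect_equal(posterior(bn, evidence, target),
                 enumerate_posterior(bn, evidence, target),
                 tolerance = 1e-10)
  }
})

test_that("inference is invariant to the elimination ordering", {
  bn <- random_bn(5, seed = 31L)
  factors <- lapply(bn$nodes, function(v)
    hazardbn:::factor_from_cpt(bn, v))
  elim <- setdiff(bn$nodes, "n1")
  r1 <- hazardbn:::eliminate_all(factors, elim)
  r2 <- hazardbn:::eliminate_all(factors, rev(elim))
  expect_equal(r1$table / sum(r1$table), r2$table / sum(r2$table),
               tolerance = 1e-10)
})

test_that("the CPT product normalizes to one and impossible evidence is
          flagged, not uniformized", {
  bn <- random_bn(5, seed = 32L)
  grid_total <- sum(vapply(bn$states$n1, function(s)
    enumerate_posterior(bn, list(), "n1")[[s]], 0))
  expect_equal(grid_total, 1, tolerance = 1e-12)

  # force an impossible configuration: P(B = 1 | A = 0) = 0
  states <- list(A = c("0", "1"), B = c("0", "1"))
  bn0 <- structure(list(
    nodes = c("A", "B"), parents = list(A = character(), B = "A"),
    states = states,
    cpts = list(
      A = array(c(1, 0), dim = 2, dimnames = list(A = states$A)),
      B = array(c(1, 0, 0.5, 0.5), dim = c(2, 2),
                dimnames = list(B = states$B, A = states$A))),
    pseudocount = 0), class = "bayes_net")
  p <- posterior(bn0, list(B = "1"), "A")
  expect_true(all(is.na(p)))
})

test_that("class prediction is argmax with a precautionary tie-break", {
  bn <- toy_outcome_bn()
  expect_equal(predict_class(bn, list(dose = "high")), "very_toxic")
  expect_equal(predict_class(bn, list(dose = "low")), "safe")
  # exact tie between toxic and safe resolves to toxic
  tie <- toy_outcome_bn(p_safe = c(low = 0.5, medium = 0.5, high = 0.5))
  tie$cpts$viability["very_toxic", ] <- 0
  tie$cpts$viability["toxic", ] <- 0.5
  expect_equal(predict_class(tie, list(dose = "medium")), "toxic")
})

test_that("structure recovery succeeds on data sampled from a known
          network", {
  truth <- random_bn(5, seed = 33L, arc_prob = 0.5)
  d <- sample_bn(truth, n = 5000, seed = 34L)
  st <- learn_structure_exact(d, max_parents = 3L)
  skel <- function(arcs) sort(paste(pmin(arcs$from, arcs$to),
                                    pmax(arcs$from, arcs$to)))
  true_arcs <- structure_arcs(truth)
  learned <- skel(structure_arcs(st))
  expect_true(all(skel(true_arcs) %in% learned))
})

test_that("the Markov blanket collects parents, children and spouses", {
  parents <- list(A = character(), B = "A", C = c("A", "D"),
                  D = character())
  st <- hazardbn:::new_structure(c("A", "B", "C", "D"), parents,
                                 states = NULL)
  expect_setequal(markov_blanket(st, "A"), c("B", "C", "D"))
  expect_setequal(markov_blanket(st, "D"), c("A", "C"))
})

test_that("structures and CPTs export to standard formats", {
  d <- sim_copy_fixture(seed = 35L)
  st <- learn_structure_hillclimb(d)
  bn <- fit_cpts(st, d)
  gpath <- withr::local_tempfile(fileext = ".graphml")
  write_structure(st, gpath)
  expect_true(file.exists(gpath))
  g <- igraph::read_graph(gpath, format = "graphml")
  expect_equal(igraph::vcount(g), 3L)
  jpath <- withr::local_tempfile(fileext = ".json")
  cpts_to_json(bn, jpath)
  parsed <- jsonlite::fromJSON(jpath, simplifyVector = FALSE)
  expect_length(parsed, 3L)
})
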