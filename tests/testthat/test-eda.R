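test_that("Spearman's rho honours monotone transforms and rank ties", {
  x <- c(0.3, 1.2, 2.5, 3.1, 4.8)
  expect_equal(spearman_rho(x, exp(x)), 1)
  expect_equal(spearman_rho(x, -x), -1)
  # sum of squared rank differences is 4: 1 - 6*4/(5*24) = 0.8
  expect_equal(spearman_rho(1:5, c(1, 3, 2, 5, 4)), 0.8)
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
  # invariance under a strictly monotone transform of either argument
  y <- c(2, 9, 4, 1, 7)
  expect_equal(spearman_rho(x, y), spearman_rho(log(x), y^3))
})

test_that("Cramer's V matches the hand-computed contingency value", {
  a <- rep(c("u", "v"), each = 25)
  b <- c(rep("x", 20), rep("y", 5), rep("x", 5), rep("y", 20))
  # expected 12.5 per cell -> chi2 = 4 * 7.5^2 / 12.5 = 18
  expect_equal(cramers_v(a, b), sqrt(18 / 50), tolerance = 1e-12)
  # perfect association and exact independence
  k3 <- rep(c("a", "b", "c"), 10)
  expect_equal(cramers_v(k3, k3), 1)
  flat <- c(rep(c("x", "y"), 10), rep(c("x", "y"), 10))
  expect_equal(cramers_v(rep(c("u", "u", "v", "v"), 10),
                         rep(c("x", "y", "x", "y"), 10)), 0)
  # symmetry and relabel invariance
  expect_equal(cramers_v(a, b), cramers_v(b, a))
  relab <- c(u = "Z9", v = "A0")[a]
  expect_equal(cramers_v(relab, b), cramers_v(a, b))
  expect_true(is.na(cramers_v(rep("only", 10), rep(c("x", "y"), 5))))
})

test_that("skewness uses the adjusted Fisher-Pearson form", {
  expect_equal(skewness(c(1, 2, 3)), 0)
  expect_equal(skewness(c(0, 0, 0, 1)), 2)
  x <- rlnorm(50)
  expect_equal(skewness(-x), -skewness(x))
  expect_true(is.na(skewness(rep(2, 10))))
})

test_that("the association matrix is symmetric with unit diagonal and
          near-zero under independence", {
  set.seed(71)
  n <- 1000
  d <- data.frame(dose = rnorm(n), core_size = runif(n),
                  coating = sample(c("HEC", "PVP"), n, TRUE),
                  assay = sample(c("MTT", "WST-1"), n, TRUE))
  am <- association_matrix(d, columns = names(d))
  expect_equal(am$matrix, t(am$matrix))
  expect_equal(unname(diag(am$matrix)), rep(1, 4))
  off <- am$matrix[upper.tri(am$matrix)]
  expect_true(all(abs(off) < 0.1))
  expect_equal(am$method["dose", "core_size"], "spearman")
  expect_equal(am$method["dose", "coating"], "cramers_v")
  expect_equal(am$method["coating", "assay"], "cramers_v")
})

test_that("mixed-type cells fall in their documented ranges on real
          pipeline output", {
  d <- finalize_features(iterative_impute(interpolate_strata(
    generate_dataset(small_generator(seed = 17L)))))
  am <- association_matrix(d)
  sp <- am$matrix[am$method == "spearman"]
  cv <- am$matrix[am$method == "cramers_v"]
  expect_true(all(sp[!is.na(sp)] >= -1 & sp[!is.na(sp)] <= 1))
  expect_true(all(cv[!is.na(cv)] >= -1e-12 & cv[!is.na(cv)] <= 1 + 1e-12))
})

test_that("the Mapper cover reaches every row and separates distant
          blobs", {
  # single row: one node, no edges
  one <- mapper_graph(matrix(1, 1, 2), lens = 0.5)
  expect_length(one$nodes, 1L)
  expect_equal(nrow(one$edges), 0L)

  set.seed(72)
  blob1 <- matrix(rnorm(40, 0, 0.02), ncol = 2)
  blob2 <- matrix(rnorm(40, 5, 0.02), ncol = 2)
  X <- rbind(blob1, blob2)
  mg <- mapper_graph(X, lens = X[, 1], n_intervals = 4, overlap = 0.3,
                     linkage_threshold = 0.3)
  # cover property
  expect_setequal(sort(unique(unlist(lapply(mg$nodes, `[[`, "members")))),
                  1:40)
  g <- mapper_to_igraph(mg)
  expect_gte(igraph::count_components(g), 2L)
})

test_that("a single wide interval reduces Mapper to single-linkage
          clustering", {
  set.seed(73)
  X <- rbind(matrix(rnorm(20, 0, 0.01), ncol = 2),
             matrix(rnorm(20, 1, 0.01), ncol = 2))
  mg <- mapper_graph(X, lens = rep(0.5, 20), n_intervals = 1,
                     overlap = 0.01, linkage_threshold = 0.4)
  hc <- stats::cutree(stats::hclust(dist(apply(X, 2, function(v)
    (v - min(v)) / (max(v) - min(v)))), method = "single"), h = 0.4)
  expect_equal(length(mg$nodes), length(unique(hc)))
  expect_equal(nrow(mg$edges), 0L)
})
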