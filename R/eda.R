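# ---------------------------------------------------------------------------
# Exploratory analysis: mixed-type association, skewness, Mapper summary
# ---------------------------------------------------------------------------

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), computed on
#' pairwise-complete observations.  A constant vector has no defined rank
#' correlation and yields `NA` (an undefined signal, not 0).
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return Coefficient in [-1, 1], or `NA_real_` when undefined.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  cor(rank(x), rank(y), method = "pearson")
}

#' Cramer's V association between two categorical vectors
#'
#' `V = sqrt(chi2 / (n * (min(r, c) - 1)))` from the r x c contingency
#' table, with the chi-squared statistic computed without continuity
#' correction and no small-sample bias correction (the classical
#' definition).  0 denotes independence, 1 perfect association.
#'
#' @param a,b Vectors of equal length; pairs with a missing member are
#'   dropped.
#' @return Coefficient in [0, 1], or `NA_real_` when either margin has a
#'   single observed state.
#' @export
cramers_v <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (!length(a)) stop("no complete pairs")
  tab <- table(a, b)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
  chi2 <- suppressWarnings(
    chisq.test(tab, correct = FALSE)$statistic)
  n <- sum(tab)
  unname(sqrt(chi2 / (n * (min(dim(tab)) - 1))))
}

#' Adjusted Fisher--Pearson skewness
#'
#' Sample-size-corrected standardized third moment,
#' `G1 = g1 * sqrt(n (n - 1)) / (n - 2)`.  Values between -2 and +2 are
#' conventionally taken as compatible with univariate normality.
#'
#' @param x Numeric vector (length >= 3 after dropping `NA`).
#' @return Skewness coefficient, or `NA_real_` for a constant vector.
#' @export
skewness <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) stop("need at least 3 observations")
  if (var(x) == 0) return(NA_real_)
  e1071::skewness(x, type = 2)
}

#' Mixed-type association matrix over dataset columns
#'
#' Numeric--numeric pairs use Spearman's rho; categorical--categorical
#' pairs Cramer's V; numeric--categorical pairs Cramer's V after tercile
#' binning the numeric member on its own distribution.  Undefined
#' associations propagate as `NA` cells.
#'
#' @param dataset data.frame.
#' @param columns Columns to include (default: all inputs plus the outcome
#'   present in the dataset).
#' @return List of class `association_matrix` with `matrix` (symmetric,
#'   unit diagonal) and `method` (per-cell tag `"spearman"` / `"cramers_v"`).
#' @export
association_matrix <- function(dataset, columns = NULL) {
  sc <- dataset_schema()
  if (is.null(columns))
    columns <- intersect(sc$column[sc$role != "identifier"], names(dataset))
  is_num <- vapply(columns, function(cl) is.numeric(dataset[[cl]]), NA)
  p <- length(columns)
  M <- matrix(NA_real_, p, p, dimnames = list(columns, columns))
  meth <- matrix(NA_character_, p, p, dimnames = list(columns, columns))
  tercile_cut <- function(v) {
    if (length(unique(v[!is.na(v)])) < 3L) return(as.character(v))
    as.character(bin_values(v, fit_quantile_bins(
      data.frame(v = v), columns = "v")$v))
  }
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) { M[i, j] <- 1; meth[i, j] <- "diag"; next }
      a <- dataset[[columns[[i]]]]; b <- dataset[[columns[[j]]]]
      if (is_num[[i]] && is_num[[j]]) {
        val <- spearman_rho(a, b); tag <- "spearman"
      } else {
        if (is_num[[i]]) a <- tercile_cut(a)
        if (is_num[[j]]) b <- tercile_cut(b)
        val <- cramers_v(a, b); tag <- "cramers_v"
      }
      M[i, j] <- M[j, i] <- val
      meth[i, j] <- meth[j, i] <- tag
    }
  }
  structure(list(matrix = M, method = meth), class = "association_matrix")
}

#' Write an association matrix to CSV and JSON
#' @param am An `association_matrix`.
#' @param csv_path,json_path Optional output paths.
#' @return `am`, invisibly.
#' @export
write_association_matrix <- function(am, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    write.csv(am$matrix, csv_path)
  if (!is.null(json_path))
    writeLines(jsonlite::toJSON(list(matrix = am$matrix,
                                     method = am$method),
                                pretty = TRUE, digits = NA, na = "null"),
               json_path)
  invisible(am)
}

# ---------------------------------------------------------------------------
# Mapper topological summary
# ---------------------------------------------------------------------------

#' Mapper graph of the experiment space
#'
#' Topological summary: the lens range is covered by `n_intervals`
#' overlapping intervals; within each preimage the min--max scaled feature
#' rows are clustered by single linkage cut at `linkage_threshold`; each
#' cluster becomes a node (with member rows, size and mean outcome colour),
#' and nodes sharing at least one row are joined by an edge.
#'
#' @param features Numeric matrix or data.frame (min--max scaled
#'   internally).
#' @param lens Per-row numeric lens value (e.g. viability or a projection).
#' @param n_intervals Number of cover intervals.
#' @param overlap Fractional overlap between consecutive intervals, in
#'   (0, 1).
#' @param linkage_threshold Single-linkage cut height in scaled-feature
#'   space.
#' @param outcome Optional per-row value averaged per node (defaults to the
#'   lens).
#' @return List of class `mapper_graph` with `nodes` (list of `members`,
#'   `size`, `mean_outcome`, `interval`) and `edges` (two-column matrix of
#'   node indices).
#' @export
mapper_graph <- function(features, lens, n_intervals = 10L, overlap = 0.3,
                         linkage_threshold = 0.5, outcome = lens) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (is.null(n) || n == 0L)
    return(structure(list(nodes = list(),
                          edges = matrix(integer(), 0, 2)),
                     class = "mapper_graph"))
  stopifnot(length(lens) == n, all(is.finite(lens)),
            overlap > 0, overlap < 1)
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]; span[span == 0] <- 1
  Xs <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/")

  lo <- min(lens); hi <- max(lens)
  width <- if (hi > lo) (hi - lo) / (n_intervals * (1 - overlap) + overlap)
           else 1
  step <- width * (1 - overlap)
  nodes <- list()
  for (i in seq_len(n_intervals)) {
    a <- lo + (i - 1) * step
    b <- a + width
    members <- which(lens >= a - 1e-12 & lens <= b + 1e-12)
    if (!length(members)) next
    if (length(members) == 1L) {
      cl <- 1L
    } else {
      hc <- hclust(dist(Xs[members, , drop = FALSE]), method = "single")
      cl <- cutree(hc, h = linkage_threshold)
    }
    for (g in sort(unique(cl))) {
      mem <- members[cl == g]
      nodes[[length(nodes) + 1L]] <- list(
        members = mem, size = length(mem),
        mean_outcome = mean(outcome[mem]), interval = i)
    }
  }
  m <- length(nodes)
  edges <- matrix(integer(), 0, 2)
  if (m > 1L) {
    pairs <- combn(m, 2)
    share <- apply(pairs, 2, function(pr)
      length(intersect(nodes[[pr[1]]]$members, nodes[[pr[2]]]$members)) > 0)
    edges <- t(pairs[, share, drop = FALSE])
  }
  structure(list(nodes = nodes, edges = edges), class = "mapper_graph")
}

#' Convert a Mapper graph to an igraph object
#' @param mg A `mapper_graph`.
#' @return An igraph graph with `size` and `mean_outcome` vertex attributes.
#' @export
mapper_to_igraph <- function(mg) {
  m <- length(mg$nodes)
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (m) {
    g <- igraph::set_vertex_attr(g, "size",
      value = vapply(mg$nodes, `[[`, 0, "size"))
    g <- igraph::set_vertex_attr(g, "mean_outcome",
      value = vapply(mg$nodes, `[[`, 0, "mean_outcome"))
  }
  if (nrow(mg$edges))
    g <- igraph::add_edges(g, t(mg$edges))
  g
}

#' Export a Mapper graph to GraphML or DOT
#' @param mg A `mapper_graph`.
#' @param path Output path ending in `.graphml` or `.dot`.
#' @return `path`, invisibly.
#' @export
write_mapper_graph <- function(mg, path) {
  g <- mapper_to_igraph(mg)
  fmt <- if (grepl("\\.dot$", path)) "dot" else "graphml"
  igraph::write_graph(g, path, format = fmt)
  invisible(path)
}
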