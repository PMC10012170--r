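# Independent oracles and fixture builders used across the suite.

# Brute-force posterior by full joint enumeration (independent of the
# variable-elimination code path).
enumerate_posterior <- function(bn, evidence, target) {
  grid <- do.call(expand.grid, c(bn$states,
                                 list(stringsAsFactors = FALSE,
                                      KEEP.OUT.ATTRS = FALSE)))
  p <- rep(1, nrow(grid))
  for (v in bn$nodes) {
    idx <- as.matrix(grid[, c(v, bn$parents[[v]]), drop = FALSE])
    p <- p * bn$cpts[[v]][idx]
  }
  keep <- rep(TRUE, nrow(grid))
  for (e in names(evidence)) keep <- keep & grid[[e]] == evidence[[e]]
  out <- vapply(bn$states[[target]], function(s)
    sum(p[keep & grid[[target]] == s]), 0)
  z <- sum(out)
  if (z <= 0) return(setNames(rep(NA_real_, length(out)),
                              bn$states[[target]]))
  out / z
}

# Random discrete network with Dirichlet CPTs (deterministic given seed).
random_bn <- function(n_nodes, seed, max_states = 3L, arc_prob = 0.4) {
  set.seed(seed)
  nodes <- paste0("n", seq_len(n_nodes))
  ord <- sample(nodes)
  parents <- setNames(replicate(n_nodes, character(), simplify = FALSE),
                      nodes)
  for (i in seq_along(ord)[-1]) {
    prev <- ord[seq_len(i - 1L)]
    parents[[ord[[i]]]] <- prev[runif(length(prev)) < arc_prob]
  }
  states <- setNames(lapply(nodes, function(v)
    paste0("s", seq_len(sample(2:max_states, 1)))), nodes)
  cpts <- list()
  for (v in nodes) {
    ps <- parents[[v]]
    r <- length(states[[v]])
    q <- prod(vapply(ps, function(p) length(states[[p]]), 0L))
    raw <- matrix(stats::rgamma(r * max(q, 1L), shape = 1), nrow = r)
    P <- sweep(raw, 2, colSums(raw), "/")
    dn <- c(list(states[[v]]), states[ps])
    names(dn) <- c(v, ps)
    cpts[[v]] <- array(P, dim = vapply(dn, length, 0L), dimnames = dn)
  }
  structure(list(nodes = nodes, parents = parents, states = states,
                 cpts = cpts, pseudocount = 0),
            class = "bayes_net")
}

# Exhaustive structure search over every DAG on the data's nodes
# (feasible for 4 nodes: 543 DAGs).  Returns the best total score and the
# number of DAGs enumerated.
exhaustive_best_score <- function(data, score = "bdeu", ess = 1) {
  nodes <- names(data)
  n <- length(nodes)
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  m <- nrow(pairs)
  score_cache <- new.env(parent = emptyenv())
  ls_cached <- function(child, ps) {
    key <- paste(child, paste(sort(ps), collapse = ","), sep = "|")
    if (is.null(score_cache[[key]]))
      score_cache[[key]] <- hazardbn::local_score(data, child, ps,
                                                  score, ess)
    score_cache[[key]]
  }
  is_acyclic <- function(adj) {
    indeg <- colSums(adj)
    left <- rep(TRUE, n)
    for (step in seq_len(n)) {
      pick <- which(left & indeg == 0)
      if (!length(pick)) return(FALSE)
      v <- pick[[1L]]
      left[[v]] <- FALSE
      indeg <- indeg - adj[v, ] * 1
      indeg[!left] <- 0L
    }
    TRUE
  }
  best <- -Inf
  n_dags <- 0L
  for (mask in 0:(2^m - 1L)) {
    sel <- bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0
    adj <- matrix(0L, n, n)
    adj[cbind(pairs$from[sel], pairs$to[sel])] <- 1L
    if (!is_acyclic(adj)) next
    n_dags <- n_dags + 1L
    tot <- sum(vapply(seq_len(n), function(v)
      ls_cached(nodes[[v]], nodes[adj[, v] == 1L]), 0))
    if (tot > best) best <- tot
  }
  list(best = best, n_dags = n_dags)
}

# Small synthetic configuration that keeps pipeline-level tests fast while
# populating all three hazard classes.
small_generator <- function(seed = 1L, noise_sd = 5) {
  generator_config(
    dose_grid_lung = c(0.5, 5, 20, 60, 100),
    dose_grid_intestinal = c(1.25, 10, 30, 100),
    replicates = 2L,
    noise_sd = noise_sd,
    seed = seed)
}

# Deterministic hand-built three-class network: dose -> viability with a
# monotone hazard gradient; used where exact posteriors must be known.
toy_outcome_bn <- function(p_safe = c(low = 0.8, medium = 0.5,
                                      high = 0.1)) {
  states <- list(dose = c("low", "medium", "high"),
                 viability = c("very_toxic", "toxic", "safe"))
  cpt_dose <- array(rep(1 / 3, 3), dim = 3,
                    dimnames = list(dose = states$dose))
  probs <- vapply(states$dose, function(b) {
    s <- p_safe[[b]]
    c(very_toxic = (1 - s) * 0.6, toxic = (1 - s) * 0.4, safe = s)
  }, numeric(3))
  cpt_v <- array(probs, dim = c(3, 3),
                 dimnames = list(viability = states$viability,
                                 dose = states$dose))
  structure(list(nodes = c("dose", "viability"),
                 parents = list(dose = character(), viability = "dose"),
                 states = states,
                 cpts = list(dose = cpt_dose, viability = cpt_v),
                 pseudocount = 0),
            class = "bayes_net")
}
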