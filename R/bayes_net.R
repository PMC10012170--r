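# ---------------------------------------------------------------------------
# Discrete Bayesian networks: constrained structure learning, CPTs,
# exact inference
# ---------------------------------------------------------------------------

#' Build a constraint set for structure learning
#'
#' @param required data.frame with columns `from`, `to`: arcs that must be
#'   present.
#' @param forbidden data.frame with columns `from`, `to`: arcs that may not
#'   be present.
#' @param roots Nodes forced to have no parents.
#' @param sink The unique node with no children (its outgoing arcs are
#'   forbidden, and learners enforce that every other node keeps a child).
#' @param tiers Named integer vector: a node of tier j may not be a parent
#'   of a node of tier i when j > i.  Unlisted nodes are unconstrained.
#' @return Object of class `constraint_set`.
#' @export
constraint_set <- function(required = NULL, forbidden = NULL,
                           roots = character(), sink = NULL,
                           tiers = integer()) {
  empty <- data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE)
  if (is.null(required)) required <- empty
  if (is.null(forbidden)) forbidden <- empty
  key <- function(d) paste(d$from, d$to, sep = "->")
  clash <- intersect(key(required), key(forbidden))
  if (length(clash))
    stop("arc(s) both required and forbidden: ",
         paste(clash, collapse = ", "))
  if (!is.null(sink) && any(required$from == sink))
    stop("sink node '", sink, "' has an outgoing required arc")
  if (length(tiers)) {
    it <- function(n) if (n %in% names(tiers)) tiers[[n]] else NA_integer_
    for (r in seq_len(nrow(required))) {
      tf <- it(required$from[[r]]); tt <- it(required$to[[r]])
      if (!is.na(tf) && !is.na(tt) && tf > tt)
        stop("required arc ", required$from[[r]], " -> ",
             required$to[[r]], " violates the tier order")
    }
  }
  structure(list(required = required, forbidden = forbidden,
                 roots = roots, sink = sink, tiers = tiers),
            class = "constraint_set")
}

#' Expert constraint set for the silver-nanoform hazard network
#'
#' Encodes the domain reasoning used to refine the learned structure:
#' exposure dose and assay are independent experimental settings (roots)
#' whose only outgoing arc feeds the viability outcome; no measured
#' property may "cause" the dose or the assay; the coating determines the
#' spherical surface area and the Ag 3d atomic concentration, while the
#' core size cannot determine the coating; descriptors measured at t0 act
#' as parents of their t24 counterparts and never vice versa; and the
#' viability outcome is the unique terminal node of the graph.
#'
#' @param nodes Node set of the network (default: the 15 final modeling
#'   features plus `viability`).
#' @return A [constraint_set()].
#' @export
asina_constraints <- function(nodes = c(final_feature_columns(),
                                        "viability")) {
  arc <- function(from, to) data.frame(from = from, to = to,
                                       stringsAsFactors = FALSE)
  required <- rbind(
    arc("dose", "viability"),
    arc("assay", "viability"),
    if (all(c("coating", "spherical_surface_area") %in% nodes))
      arc("coating", "spherical_surface_area"),
    if (all(c("coating", "ag3d_at") %in% nodes))
      arc("coating", "ag3d_at"))
  others <- setdiff(nodes, c("dose", "assay", "viability"))
  forbidden <- rbind(
    # dose and assay feed the outcome only
    if (length(others)) arc("dose", others),
    if (length(others)) arc("assay", others),
    # nothing determines the experimental settings
    arc(setdiff(nodes, "dose"), "dose"),
    arc(setdiff(nodes, "assay"), "assay"),
    # the outcome is terminal
    arc("viability", setdiff(nodes, "viability")),
    # coating is a design choice, not a consequence of the core size
    if (all(c("core_size", "coating") %in% nodes))
      arc("core_size", "coating"))
  t0 <- intersect(c("hydro_size_t0", "pdi_t0"), nodes)
  t24 <- intersect(c("hydro_size_t24", "pdi_t24"), nodes)
  if (length(t0) && length(t24))
    forbidden <- rbind(forbidden,
                       expand.grid(from = t24, to = t0,
                                   stringsAsFactors = FALSE))
  forbidden <- unique(forbidden)
  required <- unique(required)
  forbidden <- forbidden[!paste(forbidden$from, forbidden$to) %in%
                           paste(required$from, required$to), ]
  constraint_set(required = required, forbidden = forbidden,
                 roots = intersect(c("dose", "assay"), nodes),
                 sink = "viability")
}

#' Read a constraint set from a JSON or YAML file
#'
#' Expected keys: `required` / `forbidden` (lists of `[from, to]` pairs or
#' objects), `roots`, `sink`, `tiers` (name -> integer).
#'
#' @param path File path (`.json`, `.yml` or `.yaml`).
#' @return A [constraint_set()].
#' @export
read_constraints <- function(path) {
  spec <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  as_arcs <- function(x) {
    if (is.null(x) || !length(x)) return(NULL)
    if (is.data.frame(x)) return(x[, c("from", "to")])
    do.call(rbind, lapply(x, function(p)
      data.frame(from = p[[1L]], to = p[[2L]], stringsAsFactors = FALSE)))
  }
  constraint_set(required = as_arcs(spec$required),
                 forbidden = as_arcs(spec$forbidden),
                 roots = as.character(spec$roots %||% character()),
                 sink = spec$sink,
                 tiers = unlist(spec$tiers %||% integer()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

arc_allowed <- function(from, to, constraints) {
  if (is.null(constraints)) return(TRUE)
  if (from == to) return(FALSE)
  if (to %in% constraints$roots) return(FALSE)
  if (!is.null(constraints$sink) && from == constraints$sink) return(FALSE)
  if (nrow(constraints$forbidden) &&
      any(constraints$forbidden$from == from &
          constraints$forbidden$to == to)) return(FALSE)
  tiers <- constraints$tiers
  if (length(tiers) && from %in% names(tiers) && to %in% names(tiers) &&
      tiers[[from]] > tiers[[to]]) return(FALSE)
  TRUE
}

required_parents_of <- function(node, constraints) {
  if (is.null(constraints) || !nrow(constraints$required)) return(character())
  constraints$required$from[constraints$required$to == node]
}

# ---------------------------------------------------------------------------
# Scores
# ---------------------------------------------------------------------------

family_counts <- function(data, child, parents) {
  r <- nlevels(data[[child]])
  if (!length(parents)) {
    q <- 1L
    conf <- rep(1L, nrow(data))
  } else {
    sizes <- vapply(parents, function(p) nlevels(data[[p]]), 0L)
    q <- prod(sizes)
    conf <- rep(1L, nrow(data))
    mult <- 1L
    for (i in seq_along(parents)) {
      conf <- conf + (as.integer(data[[parents[[i]]]]) - 1L) * mult
      mult <- mult * sizes[[i]]
    }
  }
  idx <- (conf - 1L) * r + as.integer(data[[child]])
  matrix(tabulate(idx, nbins = r * q), nrow = r)
}

#' Decomposable local score of one node family
#'
#' BDeu (Bayesian Dirichlet equivalent uniform, equivalent sample size
#' `ess`) or BIC, computed from the counts of the child given each parent
#' configuration.  Larger is better.
#'
#' @param data data.frame of factors.
#' @param child Child node name.
#' @param parents Character vector of parent names (possibly empty).
#' @param score `"bdeu"` or `"bic"`.
#' @param ess Equivalent sample size for BDeu.
#' @return Log score (numeric scalar).
#' @export
local_score <- function(data, child, parents = character(),
                        score = c("bdeu", "bic"), ess = 1) {
  score <- match.arg(score)
  N <- family_counts(data, child, parents)
  r <- nrow(N); q <- ncol(N)
  if (score == "bdeu") {
    a_j <- ess / q
    a_jk <- ess / (r * q)
    nj <- colSums(N)
    sum(lgamma(a_j) - lgamma(a_j + nj)) +
      sum(lgamma(a_jk + N) - lgamma(a_jk))
  } else {
    nj <- colSums(N)
    ll <- sum(N[N > 0] * log(N[N > 0])) -
      sum(nj[nj > 0] * log(nj[nj > 0]))
    ll - 0.5 * log(sum(N)) * q * (r - 1)
  }
}

#' Total score of a DAG (sum of local scores)
#' @param structure A `bn_structure`.
#' @param data data.frame of factors.
#' @param score,ess As in [local_score()].
#' @return Numeric scalar.
#' @export
structure_score <- function(structure, data, score = "bdeu", ess = 1) {
  sum(vapply(structure$nodes, function(v)
    local_score(data, v, structure$parents[[v]], score, ess), 0))
}

new_structure <- function(nodes, parents, data = NULL, states = NULL) {
  if (is.null(states) && !is.null(data))
    states <- lapply(data[nodes], levels)
  structure(list(nodes = nodes, parents = parents, states = states),
            class = "bn_structure")
}

#' Arcs of a structure as a data.frame
#' @param structure A `bn_structure`.
#' @return data.frame with columns `from`, `to`.
#' @export
structure_arcs <- function(structure) {
  rows <- lapply(structure$nodes, function(v) {
    ps <- structure$parents[[v]]
    if (!length(ps)) return(NULL)
    data.frame(from = ps, to = v, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(from = character(), to = character())
  out
}

has_path <- function(parents, from, to) {
  # TRUE if a directed path from -> to exists (children direction)
  children <- list()
  for (v in names(parents)) for (p in parents[[v]])
    children[[p]] <- c(children[[p]], v)
  seen <- character(); frontier <- from
  while (length(frontier)) {
    v <- frontier[[1L]]; frontier <- frontier[-1L]
    if (v == to) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    frontier <- c(frontier, children[[v]])
  }
  FALSE
}

check_constraints_satisfiable <- function(nodes, constraints, max_parents) {
  if (is.null(constraints)) return(invisible(TRUE))
  req <- constraints$required
  for (r in seq_len(nrow(req))) {
    if (!all(c(req$from[[r]], req$to[[r]]) %in% nodes))
      stop("required arc references unknown node: ",
           req$from[[r]], " -> ", req$to[[r]])
    if (!arc_allowed(req$from[[r]], req$to[[r]], constraints))
      stop("unsatisfiable constraints: required arc ", req$from[[r]],
           " -> ", req$to[[r]], " is also excluded")
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Exact structure learning (dynamic programming over variable subsets)
# ---------------------------------------------------------------------------

#' Globally optimal DAG by dynamic programming
#'
#' Silander--Myllymaki style exact search: per node, the best scoring
#' parent set within every predecessor subset is tabulated, then the
#' optimal variable ordering is found by dynamic programming over all
#' 2^n subsets.  Constraints restrict the admissible parent sets; with an
#' empty constraint set this is the unconstrained optimum.  Exponential in
#' the node count; refuse beyond 18 nodes.
#'
#' @param data data.frame of factors (a binned dataset).
#' @param score,ess As in [local_score()].
#' @param constraints Optional [constraint_set()].
#' @param max_parents Parent-set cap for tractability.
#' @param outcome Optional node exempted from the cap (so that e.g. dose,
#'   assay and descriptor parents can coexist on the outcome).
#' @return A `bn_structure` with attribute `"score"`.
#' @export
learn_structure_exact <- function(data, score = "bdeu", ess = 1,
                                  constraints = NULL, max_parents = 4L,
                                  outcome = NULL) {
  nodes <- names(data)
  n <- length(nodes)
  if (n > 18L)
    stop("exact search is infeasible beyond 18 nodes; ",
         "use learn_structure_hillclimb()")
  check_constraints_satisfiable(nodes, constraints, max_parents)

  # per node: candidate parents and scored parent sets
  best_ps <- vector("list", n)   # per node: list(sets, scores) over cand mask
  cand_list <- vector("list", n)
  for (vi in seq_len(n)) {
    v <- nodes[[vi]]
    cand <- nodes[vapply(nodes, function(p)
      p != v && arc_allowed(p, v, constraints), NA)]
    req <- required_parents_of(v, constraints)
    cand_list[[vi]] <- cand
    cap <- if (!is.null(outcome) && v == outcome) length(cand)
           else min(max_parents, length(cand))
    if (length(req) > cap)
      stop("unsatisfiable constraints: node '", v, "' requires ",
           length(req), " parents but the cap is ", cap)
    nc <- length(cand)
    # bps over subsets of cand (bitmask): best score using parents
    # inside the mask; required parents must always be included.
    bps_score <- rep(-Inf, 2^nc)
    bps_set <- vector("list", 2^nc)
    free <- setdiff(cand, req)
    req_mask <- sum(2^(match(req, cand) - 1L))
    sets <- list(character())
    if (length(free))
      for (k in seq_len(min(cap - length(req), length(free))))
        sets <- c(sets, combn(free, k, simplify = FALSE))
    for (s in sets) {
      ps <- c(req, s)
      msk <- if (length(ps)) sum(2^(match(ps, cand) - 1L)) else 0L
      sc <- local_score(data, v, ps, score, ess)
      if (sc > bps_score[[msk + 1L]]) {
        bps_score[[msk + 1L]] <- sc
        bps_set[[msk + 1L]] <- ps
      }
    }
    # closure: best over all subsets of each mask
    if (nc > 0) for (b in seq_len(nc)) {
      bit <- 2^(b - 1L)
      for (m in 0:(2^nc - 1L)) {
        if (bitwAnd(m, bit) > 0) {
          sub <- m - bit
          if (bps_score[[sub + 1L]] > bps_score[[m + 1L]]) {
            bps_score[[m + 1L]] <- bps_score[[sub + 1L]]
            bps_set[[m + 1L]] <- bps_set[[sub + 1L]]
          }
        }
      }
    }
    best_ps[[vi]] <- list(score = bps_score, set = bps_set)
  }

  cand_mask_of <- function(vi, pred_mask) {
    # project a predecessor set (mask over nodes) onto node vi's candidates
    cand <- cand_list[[vi]]
    if (!length(cand)) return(0L)
    idx <- match(cand, nodes)
    sum(2^(seq_along(cand) - 1L)[bitwAnd(pred_mask, 2^(idx - 1L)) > 0])
  }

  # order DP over subsets of all nodes
  n_sub <- 2^n
  best <- rep(-Inf, n_sub); best[[1L]] <- 0
  last <- rep(NA_integer_, n_sub)
  for (m in 1:(n_sub - 1L)) {
    for (vi in seq_len(n)) {
      bit <- 2^(vi - 1L)
      if (bitwAnd(m, bit) == 0) next
      pred <- m - bit
      if (!is.finite(best[[pred + 1L]])) next
      s_v <- best_ps[[vi]]$score[[cand_mask_of(vi, pred) + 1L]]
      tot <- best[[pred + 1L]] + s_v
      if (tot > best[[m + 1L]]) {
        best[[m + 1L]] <- tot
        last[[m + 1L]] <- vi
      }
    }
  }
  if (!is.finite(best[[n_sub]]))
    stop("unsatisfiable constraints: no admissible ordering")
  parents <- setNames(vector("list", n), nodes)
  m <- n_sub - 1L
  while (m > 0L) {
    vi <- last[[m + 1L]]
    pred <- m - 2^(vi - 1L)
    parents[[nodes[[vi]]]] <-
      best_ps[[vi]]$set[[cand_mask_of(vi, pred) + 1L]] %||% character()
    m <- pred
  }
  st <- new_structure(nodes, parents, data)
  attr(st, "score") <- best[[n_sub]]
  st
}

# ---------------------------------------------------------------------------
# Hill-climbing structure learning
# ---------------------------------------------------------------------------

#' Greedy hill-climbing DAG search
#'
#' Add / delete / reverse moves from the constraint-seeded graph (required
#' arcs present, otherwise empty); each accepted move strictly improves the
#' score.  Ties between equally improving moves break lexicographically by
#' (move type, parent, child), making the search deterministic.  When the
#' constraint set names a sink, any other node left childless at
#' convergence is connected to the sink so the outcome remains the unique
#' terminal node.
#'
#' @param data data.frame of factors.
#' @param score,ess As in [local_score()].
#' @param constraints Optional [constraint_set()].
#' @param max_parents Parent cap per node (6, matching the reference
#'   hill-climber configuration).
#' @param seed Unused source of randomness kept for interface stability;
#'   the search is deterministic.
#' @param max_iter Cap on accepted moves.
#' @return A `bn_structure` with attributes `"score"` and `"score_trace"`.
#' @export
learn_structure_hillclimb <- function(data, score = "bdeu", ess = 1,
                                      constraints = NULL, max_parents = 6L,
                                      seed = 1L, max_iter = 500L) {
  nodes <- names(data)
  check_constraints_satisfiable(nodes, constraints, max_parents)
  parents <- setNames(replicate(length(nodes), character(),
                                simplify = FALSE), nodes)
  if (!is.null(constraints) && nrow(constraints$required))
    for (r in seq_len(nrow(constraints$required)))
      parents[[constraints$required$to[[r]]]] <-
        sort(c(parents[[constraints$required$to[[r]]]],
               constraints$required$from[[r]]))

  cache <- new.env(parent = emptyenv())
  ls_cached <- function(child, ps) {
    key <- paste(child, paste(sort(ps), collapse = ","), sep = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- local_score(data, child, ps, score, ess)
    cache[[key]]
  }
  node_score <- vapply(nodes, function(v) ls_cached(v, parents[[v]]), 0)
  trace <- sum(node_score)

  required_arc <- function(p, c_) {
    !is.null(constraints) && nrow(constraints$required) &&
      any(constraints$required$from == p & constraints$required$to == c_)
  }
  for (iter in seq_len(max_iter)) {
    best_delta <- 0; best_move <- NULL
    for (p in nodes) for (c_ in nodes) {
      if (p == c_) next
      present <- p %in% parents[[c_]]
      if (!present) {
        # add p -> c_
        if (!arc_allowed(p, c_, constraints)) next
        if (length(parents[[c_]]) >= max_parents) next
        if (has_path(parents, c_, p)) next   # would create a cycle
        delta <- ls_cached(c_, c(parents[[c_]], p)) - node_score[[c_]]
        if (delta > best_delta + 1e-9) {
          best_delta <- delta; best_move <- list("add", p, c_)
        }
      } else {
        # delete p -> c_
        if (!required_arc(p, c_)) {
          delta <- ls_cached(c_, setdiff(parents[[c_]], p)) -
            node_score[[c_]]
          if (delta > best_delta + 1e-9) {
            best_delta <- delta; best_move <- list("delete", p, c_)
          }
        }
        # reverse p -> c_ (becomes c_ -> p)
        if (!required_arc(p, c_) && arc_allowed(c_, p, constraints) &&
            length(parents[[p]]) < max_parents) {
          parents_tmp <- parents
          parents_tmp[[c_]] <- setdiff(parents_tmp[[c_]], p)
          if (!has_path(parents_tmp, p, c_)) {
            delta <- (ls_cached(c_, setdiff(parents[[c_]], p)) -
                        node_score[[c_]]) +
                     (ls_cached(p, c(parents[[p]], c_)) - node_score[[p]])
            if (delta > best_delta + 1e-9) {
              best_delta <- delta; best_move <- list("reverse", p, c_)
            }
          }
        }
      }
    }
    if (is.null(best_move)) break
    op <- best_move[[1L]]; p <- best_move[[2L]]; c_ <- best_move[[3L]]
    if (op == "add") {
      parents[[c_]] <- sort(c(parents[[c_]], p))
    } else if (op == "delete") {
      parents[[c_]] <- setdiff(parents[[c_]], p)
    } else {
      parents[[c_]] <- setdiff(parents[[c_]], p)
      parents[[p]] <- sort(c(parents[[p]], c_))
    }
    node_score[[c_]] <- ls_cached(c_, parents[[c_]])
    node_score[[p]] <- ls_cached(p, parents[[p]])
    trace <- c(trace, sum(node_score))
  }

  # sink enforcement: every non-sink node must keep a directed edge out
  if (!is.null(constraints) && !is.null(constraints$sink)) {
    sink <- constraints$sink
    children_count <- setNames(rep(0L, length(nodes)), nodes)
    for (v in nodes) for (pp in parents[[v]])
      children_count[[pp]] <- children_count[[pp]] + 1L
    for (v in sort(setdiff(nodes, sink))) {
      if (children_count[[v]] == 0L && !v %in% parents[[sink]] &&
          arc_allowed(v, sink, constraints)) {
        parents[[sink]] <- sort(c(parents[[sink]], v))
        children_count[[v]] <- 1L
      }
    }
    node_score[[sink]] <- ls_cached(sink, parents[[sink]])
    trace <- c(trace, sum(node_score))
  }
  st <- new_structure(nodes, parents, data)
  attr(st, "score") <- sum(node_score)
  attr(st, "score_trace") <- trace
  st
}

# ---------------------------------------------------------------------------
# CPT estimation and inference
# ---------------------------------------------------------------------------

#' Estimate smoothed conditional probability tables
#'
#' For every node, `P(x | parents) = (count + a) / (sum counts + a * k)`
#' per parent configuration, with pseudocount `a` (default 0.5) and `k` the
#' node's state count.  Unobserved parent configurations yield the uniform
#' smoothed row.
#'
#' @param structure A `bn_structure`.
#' @param data data.frame of factors whose levels define the state sets.
#' @param pseudocount Smoothing mass per cell.
#' @return Object of class `bayes_net`: the structure plus `cpts` (one
#'   array per node, first dimension the node itself) and `pseudocount`.
#' @export
fit_cpts <- function(structure, data, pseudocount = 0.5) {
  cpts <- list()
  for (v in structure$nodes) {
    ps <- structure$parents[[v]]
    N <- family_counts(data, v, ps)
    P <- sweep(N + pseudocount, 2,
               colSums(N) + pseudocount * nrow(N), "/")
    dims <- c(nlevels(data[[v]]),
              vapply(ps, function(p) nlevels(data[[p]]), 0L))
    dn <- c(list(levels(data[[v]])), lapply(data[ps], levels))
    names(dn) <- c(v, ps)
    cpts[[v]] <- array(P, dim = dims, dimnames = dn)
  }
  structure(list(nodes = structure$nodes, parents = structure$parents,
                 states = lapply(data[structure$nodes], levels),
                 cpts = cpts, pseudocount = pseudocount),
            class = "bayes_net")
}

# --- factor algebra on named-dimension arrays ------------------------------

new_factor <- function(vars, table) list(vars = vars, table = table)

factor_from_cpt <- function(bn, v) {
  new_factor(c(v, bn$parents[[v]]), bn$cpts[[v]])
}

factor_reduce <- function(f, evidence) {
  keep <- intersect(f$vars, names(evidence))
  if (!length(keep)) return(f)
  idx <- lapply(f$vars, function(v)
    if (v %in% keep) evidence[[v]] else TRUE)
  tab <- do.call(`[`, c(list(f$table), idx, list(drop = FALSE)))
  rem <- setdiff(f$vars, keep)
  if (!length(rem)) return(new_factor(character(), sum(tab)))
  dn <- dimnames(f$table)[match(rem, f$vars)]
  tab <- array(aperm(tab, c(match(rem, f$vars), match(keep, f$vars))),
               dim = vapply(dn, length, 0L), dimnames = setNames(dn, rem))
  new_factor(rem, tab)
}

factor_multiply <- function(f1, f2) {
  if (!length(f1$vars)) return(new_factor(f2$vars, f2$table * f1$table))
  if (!length(f2$vars)) return(new_factor(f1$vars, f1$table * f2$table))
  u <- union(f1$vars, f2$vars)
  dn <- lapply(u, function(v)
    if (v %in% f1$vars) dimnames(f1$table)[[match(v, f1$vars)]]
    else dimnames(f2$table)[[match(v, f2$vars)]])
  names(dn) <- u
  grid <- do.call(expand.grid,
                  c(dn, list(stringsAsFactors = FALSE,
                             KEEP.OUT.ATTRS = FALSE)))
  v1 <- f1$table[as.matrix(grid[f1$vars])]
  v2 <- f2$table[as.matrix(grid[f2$vars])]
  new_factor(u, array(v1 * v2, dim = vapply(dn, length, 0L),
                      dimnames = dn))
}

factor_marginalize <- function(f, var) {
  rem <- setdiff(f$vars, var)
  if (!length(rem))
    return(new_factor(character(), sum(f$table)))
  tab <- apply(f$table, match(rem, f$vars), sum)
  dn <- dimnames(f$table)[match(rem, f$vars)]
  names(dn) <- rem
  new_factor(rem, array(tab, dim = vapply(dn, length, 0L), dimnames = dn))
}

eliminate_all <- function(factors, elim_order) {
  for (v in elim_order) {
    holds <- vapply(factors, function(f) v %in% f$vars, NA)
    if (!any(holds)) next
    prod <- Reduce(factor_multiply, factors[holds])
    factors <- c(factors[!holds], list(factor_marginalize(prod, v)))
  }
  Reduce(factor_multiply, factors)
}

min_degree_order <- function(factors, elim_vars) {
  # greedy min-degree over the factor-graph moral structure
  adj <- list()
  for (f in factors) for (v in f$vars)
    adj[[v]] <- union(adj[[v]], setdiff(f$vars, v))
  order <- character()
  remaining <- elim_vars
  while (length(remaining)) {
    deg <- vapply(remaining, function(v)
      length(intersect(adj[[v]], remaining)), 0L)
    pick <- remaining[order(deg, remaining)][[1L]]
    nb <- intersect(adj[[pick]], remaining)
    for (a in nb) adj[[a]] <- union(adj[[a]], setdiff(nb, a))
    order <- c(order, pick)
    remaining <- setdiff(remaining, pick)
  }
  order
}

#' Exact posterior of a target node by variable elimination
#'
#' Conditions the network on a (partial) evidence assignment and returns
#' the exact conditional distribution of the target, using variable
#' elimination under a greedy min-degree ordering.  Evidence with zero
#' joint probability yields a vector of `NA` (an undefined signal, distinct
#' from a uniform distribution).
#'
#' @param bn A [fit_cpts()] result.
#' @param evidence Named list/vector of observed states (may be empty).
#' @param target Target node (not in the evidence).
#' @return Named probability vector over the target's states, summing to 1
#'   (or all-`NA` for impossible evidence).
#' @export
posterior <- function(bn, evidence = list(), target) {
  stopifnot(target %in% bn$nodes)
  evidence <- as.list(evidence)
  if (target %in% names(evidence))
    stop("target must not be part of the evidence")
  for (v in names(evidence)) {
    if (!v %in% bn$nodes) stop("unknown evidence node '", v, "'")
    if (!evidence[[v]] %in% bn$states[[v]])
      stop("invalid state '", evidence[[v]], "' for node '", v, "'")
  }
  factors <- lapply(bn$nodes, function(v) factor_from_cpt(bn, v))
  factors <- lapply(factors, factor_reduce, evidence = evidence)
  elim <- setdiff(bn$nodes, c(target, names(evidence)))
  res <- eliminate_all(factors, min_degree_order(factors, elim))
  tab <- res$table
  if (length(res$vars) > 1L)
    tab <- apply(tab, match(target, res$vars), sum)
  p <- as.numeric(tab)
  names(p) <- bn$states[[target]]
  z <- sum(p)
  if (z <= 0) return(setNames(rep(NA_real_, length(p)), names(p)))
  p / z
}

#' Exact joint marginal over a set of nodes
#'
#' Variable-eliminates every other node and returns the joint distribution
#' as an array with one named dimension per requested node.
#'
#' @param bn A `bayes_net`.
#' @param nodes Nodes to keep.
#' @return Array of joint probabilities (sums to 1).
#' @export
joint_marginal <- function(bn, nodes) {
  stopifnot(all(nodes %in% bn$nodes))
  factors <- lapply(bn$nodes, function(v) factor_from_cpt(bn, v))
  elim <- setdiff(bn$nodes, nodes)
  res <- eliminate_all(factors, min_degree_order(factors, elim))
  tab <- res$table
  if (!setequal(res$vars, nodes)) stop("internal: marginal mismatch")
  aperm(tab, match(nodes, res$vars))
}

#' Predict the hazard class of one binned record
#'
#' Argmax of the posterior over the outcome node, with exact ties broken
#' toward the more hazardous class (precautionary).
#'
#' @param bn A `bayes_net`.
#' @param record Named list/vector of binned states over input nodes.
#' @param target Outcome node (default `"viability"`).
#' @return The predicted class label (character scalar), or `NA` for
#'   impossible evidence.
#' @export
predict_class <- function(bn, record, target = "viability") {
  record <- as.list(record)
  record <- record[setdiff(names(record), target)]
  p <- posterior(bn, record, target)
  if (anyNA(p)) return(NA_character_)
  hz <- hazard_classes()
  ord <- if (all(names(p) %in% hz)) hz[hz %in% names(p)] else names(p)
  p <- p[ord]
  names(p)[which.max(p)]   # first max = most hazardous on ties
}

#' Predict hazard classes for every row of a binned dataset
#' @param bn A `bayes_net`.
#' @param newdata Binned data.frame containing the input nodes.
#' @param target Outcome node.
#' @return Factor of predictions with the outcome's state order.
#' @export
predict_dataset <- function(bn, newdata, target = "viability") {
  inputs <- setdiff(bn$nodes, target)
  preds <- vapply(seq_len(nrow(newdata)), function(i) {
    rec <- lapply(newdata[i, inputs, drop = FALSE], as.character)
    out <- predict_class(bn, rec, target)
    if (is.na(out)) bn$states[[target]][[1L]] else out
  }, "")
  factor(preds, levels = bn$states[[target]])
}

#' Markov blanket of a node
#'
#' Parents, children, and the children's other parents.
#'
#' @param structure A `bn_structure` or `bayes_net`.
#' @param node Node name.
#' @return Character vector of blanket members (sorted).
#' @export
markov_blanket <- function(structure, node) {
  ps <- structure$parents[[node]]
  children <- structure$nodes[vapply(structure$nodes, function(v)
    node %in% structure$parents[[v]], NA)]
  spouses <- unlist(lapply(children, function(c_) structure$parents[[c_]]))
  sort(setdiff(unique(c(ps, children, spouses)), node))
}

# ---------------------------------------------------------------------------
# Export
# ---------------------------------------------------------------------------

structure_igraph <- function(structure) {
  arcs <- structure_arcs(structure)
  igraph::graph_from_data_frame(arcs, directed = TRUE,
                                vertices = structure$nodes)
}

#' Export a structure to GraphML or DOT
#' @param structure A `bn_structure` or `bayes_net`.
#' @param path Output path ending in `.graphml` or `.dot`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  g <- structure_igraph(structure)
  fmt <- if (grepl("\\.dot$", path)) "dot" else "graphml"
  igraph::write_graph(g, path, format = fmt)
  invisible(path)
}

#' Serialize CPTs to JSON
#' @param bn A `bayes_net`.
#' @param path Optional output path.
#' @return JSON text (invisibly when written to a file).
#' @export
cpts_to_json <- function(bn, path = NULL) {
  obj <- lapply(bn$nodes, function(v) list(
    node = v, parents = bn$parents[[v]], states = bn$states[[v]],
    probabilities = bn$cpts[[v]]))
  txt <- jsonlite::toJSON(obj, pretty = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Sample records from a Bayesian network
#'
#' Ancestral sampling in topological order; used for parameter-recovery
#' experiments and for cross-checking inference.
#'
#' @param bn A `bayes_net`.
#' @param n Number of rows.
#' @param seed Integer seed.
#' @return data.frame of factors with the network's state sets.
#' @export
sample_bn <- function(bn, n, seed = 1L) {
  set.seed(seed)
  # topological order by repeated root removal
  remaining <- bn$nodes
  ord <- character()
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(v)
      !any(bn$parents[[v]] %in% remaining), NA)]
    ord <- c(ord, ready)
    remaining <- setdiff(remaining, ready)
  }
  out <- setNames(vector("list", length(bn$nodes)), bn$nodes)
  for (v in ord) {
    ps <- bn$parents[[v]]
    states <- bn$states[[v]]
    if (!length(ps)) {
      out[[v]] <- sample(states, n, replace = TRUE,
                         prob = as.numeric(bn$cpts[[v]]))
    } else {
      draw <- character(n)
      cfg <- do.call(paste, c(lapply(out[ps], as.character), sep = "\r"))
      for (k in unique(cfg)) {
        rows <- which(cfg == k)
        st <- strsplit(k, "\r", fixed = TRUE)[[1L]]
        idx <- c(list(TRUE), as.list(st))
        pr <- as.numeric(do.call(`[`, c(list(bn$cpts[[v]]), idx)))
        draw[rows] <- sample(states, length(rows), replace = TRUE,
                             prob = pr)
      }
      out[[v]] <- draw
    }
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  for (v in bn$nodes) df[[v]] <- factor(df[[v]], levels = bn$states[[v]])
  df
}
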