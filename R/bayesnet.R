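#' @section Network representation:
#' The hourly fall-risk model is a discrete Bayesian network over concept
#' nodes grouped into constructs (demographics/administrative, KPCS,
#' medication, nursing intervention, nursing assessment & diagnosis, and the
#' heuristic fall-risk tool), with one binary target node,
#' `fall_next_hour`. The packaged default structure is a three-layer tree:
#' the target is the root, latent construct-summary nodes sit below it, and
#' observable feature nodes hang off their summary (single-feature constructs
#' attach directly to the target). Any alternative edge list can be supplied
#' as a YAML config; inference is exact for any DAG.
#' @name fallcds-network
NULL

#' Build and validate a network specification
#'
#' Reads a YAML network description with a `nodes` list (each node: `name`,
#' `states`, `construct`, and optionally `role` = `"summary"`,
#' `risk_category`, `active_states`) and an `edges` list of `[parent, child]`
#' pairs, and checks that it is a DAG with exactly one binary target node.
#'
#' @param path YAML file, or a list already parsed from one.
#' @return an object of class `fp_network_spec`.
#' @export
build_network <- function(path) {
  raw <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(raw$nodes) || !length(raw$nodes)) stop("network spec has no nodes")
  seen_names <- vapply(raw$nodes, function(nd) as.character(nd$name %||% ""), "")
  if (anyDuplicated(seen_names))
    stop("duplicate node name: ", seen_names[duplicated(seen_names)][1])
  nodes <- list()
  for (nd in raw$nodes) {
    if (is.null(nd$name) || is.null(nd$states) || is.null(nd$construct))
      stop("every node needs name, states and construct")
    st <- as.character(unlist(nd$states))
    if (length(st) < 2 || anyDuplicated(st))
      stop("node '", nd$name, "' needs >= 2 distinct states")
    nodes[[nd$name]] <- list(
      name = nd$name, states = st, construct = nd$construct,
      role = nd$role %||% if (identical(nd$construct, "target")) "target" else "feature",
      risk_category = nd$risk_category %||% NA_character_,
      active_states = as.character(unlist(nd$active_states %||% st[-1])))
  }

  tgt <- names(nodes)[vapply(nodes, function(n) n$construct == "target", logical(1))]
  if (length(tgt) != 1)
    stop("network must declare exactly one target node, found ", length(tgt))
  if (length(nodes[[tgt]]$states) != 2)
    stop("target node must be binary")

  edges <- do.call(rbind, lapply(raw$edges, function(e) {
    e <- as.character(unlist(e))
    if (length(e) != 2) stop("edges must be [parent, child] pairs")
    e
  }))
  edges <- if (is.null(edges)) {
    matrix(character(0), 0, 2, dimnames = list(NULL, c("parent", "child")))
  } else {
    colnames(edges) <- c("parent", "child")
    edges
  }
  unknown <- setdiff(c(edges), names(nodes))
  if (length(unknown)) stop("edge references unknown node: ", unknown[1])

  spec <- structure(list(nodes = nodes, edges = edges, target = tgt),
                    class = "fp_network_spec")
  cyc <- find_cycle(spec)
  if (!is.null(cyc))
    stop("network is not a DAG; cycle: ", paste(cyc, collapse = " -> "))
  spec
}

#' Packaged default fall-risk network specification
#' @return an `fp_network_spec` (three-layer tree, 6 feature constructs).
#' @export
fp_network_spec <- function() {
  build_network(system.file("extdata", "network_default.yaml", package = "fallcds"))
}

node_parents <- function(spec, v) spec$edges[spec$edges[, "child"] == v, "parent"]
node_children <- function(spec, v) spec$edges[spec$edges[, "parent"] == v, "child"]

# Kahn topological sort; returns NULL plus attr "cycle" when cyclic
topo_sort <- function(spec) {
  nms <- names(spec$nodes)
  indeg <- vapply(nms, function(v) length(node_parents(spec, v)), integer(1))
  order <- character(0)
  queue <- nms[indeg == 0]
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in node_children(spec, v)) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(nms)) return(NULL)
  order
}

find_cycle <- function(spec) {
  if (!is.null(topo_sort(spec))) return(NULL)
  # nodes the topological sort cannot place form the cyclic core; walking
  # parent links inside the core must revisit a node
  nms <- names(spec$nodes)
  indeg <- vapply(nms, function(v) length(node_parents(spec, v)), integer(1))
  queue <- nms[indeg == 0]
  placed <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    placed <- c(placed, v)
    for (ch in node_children(spec, v)) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0) queue <- c(queue, ch)
    }
  }
  core <- setdiff(nms, placed)
  path <- core[1]
  repeat {
    p <- intersect(node_parents(spec, path[length(path)]), core)[1]
    if (p %in% path)
      return(c(p, rev(path[seq(which(path == p), length(path))])))
    path <- c(path, p)
  }
}

#' Drop one construct from a network specification
#'
#' Removes every node tagged with the construct (feature and summary nodes)
#' together with all incident edges. Used for the with/without-heuristic
#' model contrast and for sites lacking a feature set.
#'
#' @param spec an `fp_network_spec`.
#' @param construct construct label; must not be `"target"`.
#' @return a validated `fp_network_spec`.
#' @export
ablate_construct <- function(spec, construct) {
  if (identical(construct, "target")) stop("cannot ablate the target")
  drop <- names(spec$nodes)[vapply(spec$nodes, function(n)
    identical(n$construct, construct), logical(1))]
  if (!length(drop)) return(spec)
  keep_nodes <- spec$nodes[setdiff(names(spec$nodes), drop)]
  e <- spec$edges
  e <- e[!(e[, "parent"] %in% drop | e[, "child"] %in% drop), , drop = FALSE]
  build_network(list(
    nodes = lapply(keep_nodes, function(n)
      list(name = n$name, states = as.list(n$states), construct = n$construct,
           role = n$role, risk_category = n$risk_category,
           active_states = as.list(n$active_states))),
    edges = lapply(seq_len(nrow(e)), function(i) as.list(e[i, ]))))
}

#' Keep only the given constructs (plus the target)
#' @param spec an `fp_network_spec`.
#' @param constructs constructs to retain.
#' @return an `fp_network_spec`.
#' @export
keep_constructs <- function(spec, constructs) {
  all_c <- setdiff(unique(vapply(spec$nodes, `[[`, "", "construct")), "target")
  for (cstr in setdiff(all_c, constructs)) spec <- ablate_construct(spec, cstr)
  spec
}

#' Construct labels present in a specification
#' @param spec an `fp_network_spec`.
#' @param roles node roles to include (default feature nodes only).
#' @return character vector of construct labels.
#' @export
network_constructs <- function(spec, roles = "feature") {
  unique(vapply(spec$nodes[vapply(spec$nodes, function(n) n$role %in% roles,
                                  logical(1))], `[[`, "", "construct"))
}

#' Fit conditional probability tables by smoothed maximum likelihood
#'
#' For each node, tallies the training rows over the node's states within
#' each parent-state combination and normalises with additive smoothing
#' `alpha`. Parent combinations never seen in the data get a uniform row when
#' `alpha = 0`.
#'
#' @param spec an `fp_network_spec`.
#' @param train data frame holding one column per network node (discrete
#'   values matching the declared states).
#' @param alpha additive smoothing pseudo-count (default 1).
#' @return an object of class `fp_fitted_network` with components `spec`,
#'   `tables` (one array per node, first dimension the node itself) and
#'   `alpha`.
#' @export
fit_parameters <- function(spec, train, alpha = 1) {
  stopifnot(inherits(spec, "fp_network_spec"), alpha >= 0)
  missing_cols <- setdiff(names(spec$nodes), names(train))
  if (length(missing_cols))
    stop("training data lacks columns for node(s): ",
         paste(missing_cols, collapse = ", "))
  tables <- list()
  for (v in names(spec$nodes)) {
    sts <- spec$nodes[[v]]$states
    bad <- !is.na(train[[v]]) & !train[[v]] %in% sts
    if (any(bad))
      stop("column '", v, "' contains values outside its declared states: ",
           paste(utils::head(unique(train[[v]][bad]), 3), collapse = ", "))
    pars <- node_parents(spec, v)
    fs <- c(list(factor(train[[v]], levels = sts)),
            lapply(pars, function(p)
              factor(train[[p]], levels = spec$nodes[[p]]$states)))
    counts <- table(fs, dnn = c(v, pars)) + alpha
    counts <- array(counts, dim = dim(counts), dimnames = dimnames(counts))
    if (length(pars) == 0) {
      tab <- if (sum(counts) == 0) counts + 1 / length(sts) else counts / sum(counts)
    } else {
      tot <- apply(counts, seq_along(dim(counts))[-1], sum)
      tot_arr <- array(rep(tot, each = length(sts)), dim = dim(counts))
      tab <- counts / tot_arr
      if (any(tot == 0)) { # unseen parent combination: uniform row
        unif <- array(rep(tot == 0, each = length(sts)), dim = dim(counts))
        tab[unif] <- 1 / length(sts)
      }
      dimnames(tab) <- dimnames(counts)
    }
    tables[[v]] <- tab
  }
  structure(list(spec = spec, tables = tables, alpha = alpha),
            class = "fp_fitted_network")
}

#' @export
print.fp_fitted_network <- function(x, ...) {
  cat("Fitted fall-risk network:", length(x$spec$nodes), "nodes,",
      nrow(x$spec$edges), "edges, alpha =", x$alpha, "\n")
  invisible(x)
}

## ---- factor algebra for variable elimination ------------------------------

n_states <- function(spec, v) length(spec$nodes[[v]]$states)

factor_from_cpt <- function(net, v) {
  pars <- node_parents(net$spec, v)
  list(vars = c(v, pars), tab = net$tables[[v]])
}

factor_reduce <- function(f, evidence) {
  hit <- intersect(f$vars, names(evidence))
  if (!length(hit)) return(f)
  idx <- lapply(f$vars, function(v)
    if (v %in% hit) evidence[[v]] else TRUE)
  tab <- do.call(`[`, c(list(f$tab), idx, list(drop = FALSE)))
  keep <- !(f$vars %in% hit)
  newdim <- dim(tab)[keep]
  if (!length(newdim)) newdim <- 1L
  tab <- array(tab, dim = newdim,
               dimnames = if (any(keep)) dimnames(f$tab)[keep] else NULL)
  list(vars = f$vars[keep], tab = tab)
}

factor_product <- function(f1, f2, spec) {
  u <- union(f1$vars, f2$vars)
  if (!length(u)) return(list(vars = character(0),
                              tab = array(as.numeric(f1$tab) * as.numeric(f2$tab), 1)))
  expand <- function(f) {
    if (!length(f$vars)) {
      t <- array(as.numeric(f$tab),
                 dim = vapply(u, n_states, 0L, spec = spec),
                 dimnames = lapply(u, function(v) spec$nodes[[v]]$states))
      names(dimnames(t)) <- u
      return(t)
    }
    t <- f$tab
    for (m in setdiff(u, f$vars)) {
      t <- outer(t, rep(1, n_states(spec, m)))
    }
    t <- array(t, dim = c(vapply(f$vars, n_states, 0L, spec = spec),
                          vapply(setdiff(u, f$vars), n_states, 0L, spec = spec)))
    aperm(t, match(u, c(f$vars, setdiff(u, f$vars))))
  }
  tab <- expand(f1) * expand(f2)
  tab <- array(tab, dim = vapply(u, n_states, 0L, spec = spec),
               dimnames = lapply(u, function(v) spec$nodes[[v]]$states))
  list(vars = u, tab = tab)
}

factor_marginalize <- function(f, v, spec) {
  i <- match(v, f$vars)
  keep <- seq_along(f$vars)[-i]
  if (!length(keep)) {
    return(list(vars = character(0), tab = array(sum(f$tab), 1)))
  }
  tab <- apply(f$tab, keep, sum)
  tab <- array(tab, dim = vapply(f$vars[keep], n_states, 0L, spec = spec),
               dimnames = lapply(f$vars[keep], function(x) spec$nodes[[x]]$states))
  list(vars = f$vars[keep], tab = tab)
}

# Variable elimination: unnormalised distribution over `query` given evidence.
# Sum of the returned table equals P(evidence).
ve_query <- function(net, query, evidence = list()) {
  spec <- net$spec
  factors <- lapply(names(spec$nodes), function(v) factor_from_cpt(net, v))
  if (length(evidence))
    factors <- lapply(factors, factor_reduce, evidence = evidence)
  elim <- setdiff(names(spec$nodes), c(query, names(evidence)))
  while (length(elim)) {
    # greedy: eliminate the variable whose combined factor is smallest
    size_of <- vapply(elim, function(v) {
      vars <- unique(unlist(lapply(factors,
                                   function(f) if (v %in% f$vars) f$vars)))
      prod(vapply(vars, n_states, 0L, spec = spec))
    }, 0)
    v <- elim[which.min(size_of)]
    inv <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod_f <- Reduce(function(a, b) factor_product(a, b, spec), factors[inv])
    factors <- c(factors[!inv], list(factor_marginalize(prod_f, v, spec)))
    elim <- setdiff(elim, v)
  }
  out <- Reduce(function(a, b) factor_product(a, b, spec), factors)
  # any remaining constant factors have been absorbed; reorder to query
  if (length(query) && !identical(out$vars, query)) {
    perm <- match(query, out$vars)
    out$tab <- aperm(out$tab, perm)
    out$vars <- query
    dimnames(out$tab) <- lapply(query, function(v) spec$nodes[[v]]$states)
  }
  out
}

#' Posterior fall risk for one observation
#'
#' Computes the exact posterior probability of the positive target state
#' given the evidence, by variable elimination, and extracts the associated
#' risk factors: evidence findings whose single-finding likelihood ratio for
#' the target exceeds 1 (ie findings that on their own raise the posterior).
#'
#' @param net an `fp_fitted_network`.
#' @param evidence named list or character vector mapping feature nodes to
#'   observed states; must not include the target.
#' @return list with `probability`, `prior`, and `active_risk_factors` (a
#'   data frame with `node`, `state`, `risk_category`, `lr`).
#' @export
posterior_fall_risk <- function(net, evidence = list()) {
  spec <- net$spec
  evidence <- as.list(evidence)
  if (spec$target %in% names(evidence))
    stop("evidence must not include the target node")
  for (v in names(evidence)) {
    if (!v %in% names(spec$nodes)) stop("evidence names unknown node: ", v)
    if (!evidence[[v]] %in% spec$nodes[[v]]$states)
      stop("invalid state '", evidence[[v]], "' for node '", v, "'")
  }
  prior_f <- ve_query(net, spec$target)
  prior <- as.numeric(prior_f$tab[2] / sum(prior_f$tab))
  post_f <- ve_query(net, spec$target, evidence)
  z <- sum(post_f$tab)
  if (z <= 0)
    stop("evidence has probability zero under the fitted network (inconsistent evidence)")
  p <- as.numeric(post_f$tab[2] / z)

  arf <- data.frame(node = character(0), state = character(0),
                    risk_category = character(0), lr = numeric(0))
  prior_odds <- prior / (1 - prior)
  for (v in names(evidence)) {
    f1 <- ve_query(net, spec$target, evidence[v])
    p1 <- as.numeric(f1$tab[2] / sum(f1$tab))
    lr <- (p1 / (1 - p1)) / prior_odds
    if (is.finite(lr) && lr > 1)
      arf <- rbind(arf, data.frame(node = v, state = as.character(evidence[[v]]),
                                   risk_category = spec$nodes[[v]]$risk_category,
                                   lr = lr))
  }
  arf <- arf[order(-arf$lr), ]
  rownames(arf) <- NULL
  list(probability = p, prior = prior, active_risk_factors = arf)
}

## ---- batch prediction -----------------------------------------------------

is_tree <- function(spec) {
  nms <- names(spec$nodes)
  npar <- vapply(nms, function(v) length(node_parents(spec, v)), integer(1))
  sum(npar == 0) == 1 && all(npar[npar != 0] == 1) && !is.null(topo_sort(spec))
}

# likelihood message from node v to its parent, vectorised over rows:
# matrix [n_rows x n_states(parent)]
tree_message <- function(net, v, data, n) {
  spec <- net$spec
  sts <- spec$nodes[[v]]$states
  L <- matrix(1, n, length(sts))
  if (v %in% names(data)) {
    idx <- match(data[[v]], sts)
    obs <- !is.na(idx)
    L[obs, ] <- 0
    L[cbind(which(obs), idx[obs])] <- 1
  }
  for (ch in node_children(spec, v))
    L <- L * tree_message(net, ch, data, n)
  cptm <- net$tables[[v]] # states(v) x states(parent)
  L %*% cptm
}

#' Batch posterior fall risk
#'
#' Computes the posterior probability of the positive target state for every
#' row of `newdata`. Columns matching network nodes are used as evidence
#' (`NA` = unobserved); other nodes are marginalised out. Tree-structured
#' networks use a vectorised message-passing path; general DAGs fall back to
#' per-unique-row variable elimination. Both paths give identical exact
#' posteriors.
#'
#' @param net an `fp_fitted_network`.
#' @param newdata data frame of observations.
#' @return numeric vector of posterior probabilities.
#' @export
predict_risk <- function(net, newdata) {
  spec <- net$spec
  tgt <- spec$target
  ev_cols <- intersect(setdiff(names(spec$nodes), tgt), names(newdata))
  n <- nrow(newdata)
  if (is_tree(spec) && !length(node_parents(spec, tgt))) {
    L <- matrix(1, n, 2)
    for (ch in node_children(spec, tgt))
      L <- L * tree_message(net, ch, newdata[ev_cols], n)
    prior <- as.numeric(net$tables[[tgt]])
    post <- t(t(L) * prior)
    z <- rowSums(post)
    if (any(z <= 0)) stop("evidence with probability zero in row ",
                          which(z <= 0)[1])
    return(post[, 2] / z)
  }
  key <- do.call(paste, c(newdata[ev_cols], sep = "\r"))
  out <- numeric(n)
  for (k in unique(key)) {
    i <- which(key == k)[1]
    ev <- as.list(newdata[i, ev_cols, drop = FALSE])
    ev <- ev[!is.na(unlist(ev))]
    f <- ve_query(net, tgt, ev)
    z <- sum(f$tab)
    if (z <= 0) stop("evidence with probability zero in row ", i)
    out[key == k] <- as.numeric(f$tab[2] / z)
  }
  out
}

#' Ancestral sampling from a fitted network
#'
#' @param net an `fp_fitted_network`.
#' @param n number of rows.
#' @param seed integer seed.
#' @return data frame with one column per node.
#' @export
sample_network <- function(net, n, seed = 1) {
  spec <- net$spec
  ord <- topo_sort(spec)
  set.seed(seed)
  out <- list()
  for (v in ord) {
    sts <- spec$nodes[[v]]$states
    pars <- node_parents(spec, v)
    tab <- net$tables[[v]]
    if (!length(pars)) {
      out[[v]] <- sample(sts, n, replace = TRUE, prob = as.numeric(tab))
    } else {
      pidx <- lapply(pars, function(p) match(out[[p]], spec$nodes[[p]]$states))
      cptm <- array(tab, dim = c(length(sts), prod(dim(tab)[-1])))
      flat <- 1
      mult <- 1
      for (j in seq_along(pars)) {
        flat <- flat + (pidx[[j]] - 1) * mult
        mult <- mult * n_states(spec, pars[j])
      }
      u <- stats::runif(n)
      cum <- apply(cptm, 2, cumsum)
      pick <- integer(n)
      for (g in unique(flat)) {
        rows <- flat == g
        pick[rows] <- findInterval(u[rows], cum[, g]) + 1L
      }
      pick[pick > length(sts)] <- length(sts)
      out[[v]] <- sts[pick]
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Variance reduction of the fall posterior attributable to one construct
#'
#' The contribution measure for the sensitivity analysis: with binary target
#' prior `p`, prior variance is `p(1-p)`; the construct's variance reduction
#' is `Var(T) - sum_c P(C=c) Var(T | C=c)`, summing over the joint states
#' `c` of the construct's observable feature nodes (enumerated exactly).
#' A construct independent of the target reduces no variance; one that fully
#' determines the target removes all of it.
#'
#' @param net an `fp_fitted_network`.
#' @param construct construct label with at least one feature node.
#' @param cap maximum joint state-space size to enumerate (default 1e5).
#' @return nonnegative scalar.
#' @export
variance_reduction <- function(net, construct, cap = 1e5) {
  spec <- net$spec
  vars <- names(spec$nodes)[vapply(spec$nodes, function(nd)
    identical(nd$construct, construct) && nd$role == "feature", logical(1))]
  if (!length(vars)) stop("construct '", construct, "' has no feature nodes")
  space <- prod(vapply(vars, n_states, 0L, spec = spec))
  if (space > cap)
    stop("joint state space of construct '", construct, "' has ", space,
         " states, above the cap of ", cap,
         "; enumerate a smaller construct or raise `cap`")
  prior_f <- ve_query(net, spec$target)
  p0 <- as.numeric(prior_f$tab[2] / sum(prior_f$tab))
  grid <- expand.grid(lapply(vars, function(v) spec$nodes[[v]]$states),
                      stringsAsFactors = FALSE)
  names(grid) <- vars
  exp_var <- 0
  for (i in seq_len(nrow(grid))) {
    ev <- as.list(grid[i, , drop = FALSE])
    f <- ve_query(net, spec$target, ev)
    pz <- sum(f$tab)
    if (pz <= 0) next
    pc <- as.numeric(f$tab[2] / pz)
    exp_var <- exp_var + pz * pc * (1 - pc)
  }
  max(0, p0 * (1 - p0) - exp_var)
}

#' Variance-reduction profile across all constructs
#'
#' @param net an `fp_fitted_network`.
#' @param cap passed to [variance_reduction()].
#' @return data frame with `construct`, `vr` (raw) and `share` (fraction of
#'   the total across constructs; the shares sum to 1 when any construct has
#'   positive reduction).
#' @export
vr_profile <- function(net, cap = 1e5) {
  cons <- network_constructs(net$spec)
  vr <- vapply(cons, function(cstr) variance_reduction(net, cstr, cap), 0)
  tot <- sum(vr)
  data.frame(construct = cons, vr = as.numeric(vr),
             share = if (tot > 0) as.numeric(vr) / tot else rep(NA_real_, length(vr)),
             row.names = NULL, stringsAsFactors = FALSE)
}
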