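# Independent oracles used to check the implementation by a different route.
# These deliberately use naive, exhaustive algorithms.

# full-joint table of a fitted network by direct enumeration
enum_joint <- function(net) {
  spec <- net$spec
  nms <- names(spec$nodes)
  grid <- expand.grid(lapply(nms, function(v) spec$nodes[[v]]$states),
                      stringsAsFactors = FALSE)
  names(grid) <- nms
  p <- rep(1, nrow(grid))
  for (v in nms) {
    pars <- spec$edges[spec$edges[, "child"] == v, "parent"]
    tab <- net$tables[[v]]
    idx <- cbind(match(grid[[v]], spec$nodes[[v]]$states))
    for (pp in pars) idx <- cbind(idx, match(grid[[pp]], spec$nodes[[pp]]$states))
    p <- p * tab[idx]
  }
  grid$p <- p
  grid
}

# posterior P(target = positive | evidence) by brute-force enumeration
enum_posterior <- function(net, evidence = list()) {
  j <- enum_joint(net)
  keep <- rep(TRUE, nrow(j))
  for (v in names(evidence)) keep <- keep & j[[v]] == evidence[[v]]
  tgt <- net$spec$target
  pos <- net$spec$nodes[[tgt]]$states[2]
  z <- sum(j$p[keep])
  if (z == 0) return(NA_real_)
  sum(j$p[keep & j[[tgt]] == pos]) / z
}

# variance reduction of one construct from the enumerated joint
enum_variance_reduction <- function(net, construct) {
  spec <- net$spec
  j <- enum_joint(net)
  tgt <- spec$target
  pos <- spec$nodes[[tgt]]$states[2]
  vars <- names(spec$nodes)[vapply(spec$nodes, function(nd)
    identical(nd$construct, construct) && nd$role == "feature", logical(1))]
  p0 <- sum(j$p[j[[tgt]] == pos])
  key <- do.call(paste, c(j[vars], sep = "\r"))
  ev <- 0
  for (k in unique(key)) {
    pz <- sum(j$p[key == k])
    if (pz == 0) next
    pc <- sum(j$p[key == k & j[[tgt]] == pos]) / pz
    ev <- ev + pz * pc * (1 - pc)
  }
  p0 * (1 - p0) - ev
}

# AUROC by exhaustive pair counting (concordant + half ties)
pair_auroc <- function(scores, labels) {
  y <- if (is.numeric(labels)) labels else as.integer(labels == sort(unique(labels))[2])
  sp <- scores[y == 1]; sn <- scores[y == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Youden threshold by exhaustive scan over the same candidate set
scan_threshold <- function(scores, labels) {
  y <- if (is.numeric(labels)) labels else as.integer(labels == sort(unique(labels))[2])
  s <- sort(unique(scores))
  cand <- if (length(s) == 1) s else
    c(s[1] - 1, (s[-length(s)] + s[-1]) / 2, s[length(s)] + 1)
  j <- vapply(cand, function(t)
    mean(scores[y == 1] >= t) + mean(scores[y == 0] < t) - 1, 0)
  cand[which.max(j)]
}

# random discrete network (<= max_nodes nodes, joint state space capped) with
# random Dirichlet-like CPTs, as a fitted-network object
random_network <- function(seed, max_nodes = 12, joint_cap = 30000) {
  set.seed(seed)
  repeat {
    n <- sample(4:max_nodes, 1)
    nst <- c(2L, sample(2:3, n - 1, replace = TRUE))
    if (prod(nst) <= joint_cap) break
  }
  nms <- c("t", paste0("x", seq_len(n - 1)))
  ord <- sample(n)  # topological position of each node
  nodes <- lapply(seq_len(n), function(i)
    list(name = nms[i], states = as.list(paste0("s", seq_len(nst[i]))),
         construct = if (i == 1) "target" else paste0("c", 1 + (i %% 3)),
         role = if (i == 1) "target" else "feature"))
  edges <- list()
  pos <- order(ord)  # nodes in topological order
  for (j in 2:n) {
    child <- pos[j]
    prev <- pos[seq_len(j - 1)]
    npar <- stats::rbinom(1, min(2, length(prev)), 0.5)
    if (npar > 0)
      for (p in prev[sample.int(length(prev), npar)])
        edges <- c(edges, list(list(nms[p], nms[child])))
  }
  spec <- fallcds::build_network(list(nodes = nodes, edges = edges))
  tables <- list()
  for (v in names(spec$nodes)) {
    pars <- spec$edges[spec$edges[, "child"] == v, "parent"]
    dims <- c(length(spec$nodes[[v]]$states),
              vapply(pars, function(p) length(spec$nodes[[p]]$states), 0L))
    tab <- array(stats::rgamma(prod(dims), 1) + 0.05, dim = dims,
                 dimnames = c(list(spec$nodes[[v]]$states),
                              lapply(pars, function(p) spec$nodes[[p]]$states)))
    if (length(dims) == 1) tab <- tab / sum(tab)
    else {
      tot <- apply(tab, seq_along(dims)[-1], sum)
      tab <- tab / array(rep(tot, each = dims[1]), dim = dims)
    }
    tables[[v]] <- tab
  }
  structure(list(spec = spec, tables = tables, alpha = 0),
            class = "fp_fitted_network")
}

# random evidence on a subset of non-target nodes
random_evidence <- function(net, seed) {
  set.seed(seed)
  spec <- net$spec
  cand <- setdiff(names(spec$nodes), spec$target)
  take <- cand[stats::runif(length(cand)) < 0.5]
  ev <- lapply(take, function(v) sample(spec$nodes[[v]]$states, 1))
  names(ev) <- take
  ev
}
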