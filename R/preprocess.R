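#' Apply the cohort eligibility criteria
#'
#' Keeps stays of adults (age >= 18) admitted for at least 24 hours with no
#' psychiatric, obstetric, emergency or pediatric condition. Each dropped
#' stay is labelled with its first failing rule, checked in the order age,
#' duration, condition; a missing age is reported as `missing_age`.
#'
#' @param stays data frame with `age`, `admit_time`, `discharge_time`,
#'   `excluded_condition` (NA when none).
#' @return list with `kept` (data frame) and `dropped` (data frame with an
#'   added `reason` column).
#' @export
apply_inclusion_exclusion <- function(stays) {
  dur_h <- as.numeric(difftime(stays$discharge_time, stays$admit_time, units = "hours"))
  reason <- rep(NA_character_, nrow(stays))
  reason[is.na(reason) & is.na(stays$age)] <- "missing_age"
  reason[is.na(reason) & stays$age < 18] <- "age"
  reason[is.na(reason) & dur_h < 24] <- "duration"
  reason[is.na(reason) & !is.na(stays$excluded_condition)] <- "condition"
  dropped <- stays[!is.na(reason), , drop = FALSE]
  dropped$reason <- reason[!is.na(reason)]
  rownames(dropped) <- NULL
  kept <- stays[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, dropped = dropped)
}

#' Build the modelling feature matrix from a cohort
#'
#' Restricts the hourly observations to eligible stays, keeps the columns
#' matching the network's feature nodes (plus continuous `age` and the
#' binary label), and attaches a schema (column -> construct, kind) as the
#' `"schema"` attribute. Rows with a missing label are dropped. Latent
#' construct-summary columns are derived later, after any class balancing,
#' with [derive_construct_summaries()], so that synthetic rows stay
#' internally consistent.
#'
#' @param cohort an `fp_cohort`.
#' @param spec an `fp_network_spec` (defaults to the packaged network,
#'   ablated of KPCS when the cohort's site lacks it).
#' @return data frame with attribute `"schema"`; includes `stay_id` for
#'   group-aware splitting.
#' @export
build_feature_matrix <- function(cohort, spec = NULL) {
  if (is.null(spec)) {
    spec <- fp_network_spec()
    if (!isTRUE(cohort$profile$kpcs_available))
      spec <- ablate_construct(spec, "kpcs")
  }
  filt <- apply_inclusion_exclusion(cohort$stays)
  obs <- cohort$observations[cohort$observations$stay_id %in% filt$kept$stay_id, ]
  feat <- setdiff(names(spec$nodes)[vapply(spec$nodes, function(n)
    n$role == "feature", logical(1))], spec$target)
  miss <- setdiff(feat, names(obs))
  if (length(miss))
    stop("cohort observations lack feature column(s): ",
         paste(miss, collapse = ", "))
  aux <- intersect("heuristic_score", names(obs))
  X <- obs[, c("stay_id", feat, "age", aux), drop = FALSE]
  X$fall_next_hour <- obs$fall_next_hour
  X <- X[!is.na(X$fall_next_hour), , drop = FALSE]
  schema <- data.frame(
    column = setdiff(names(X), "stay_id"),
    construct = vapply(setdiff(names(X), "stay_id"), function(cn) {
      if (cn == "age") "demographics_admin"
      else if (cn == "heuristic_score") "heuristic_tool"
      else if (cn %in% names(spec$nodes)) spec$nodes[[cn]]$construct
      else "derived"
    }, ""),
    kind = vapply(setdiff(names(X), "stay_id"), function(cn)
      if (cn %in% c("age", "heuristic_score")) "continuous" else "nominal", ""),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(X, "schema") <- schema
  rownames(X) <- NULL
  X
}

#' Derive latent construct-summary columns
#'
#' For every summary node in the spec, counts how many of its child feature
#' columns are in an active state and bands the count as
#' `none` / `one` / `multi` (0, 1, 2+).
#'
#' @param X data frame holding the feature columns.
#' @param spec an `fp_network_spec`.
#' @return `X` with one added column per summary node.
#' @export
derive_construct_summaries <- function(X, spec) {
  for (v in names(spec$nodes)) {
    if (spec$nodes[[v]]$role != "summary") next
    kids <- intersect(node_children(spec, v), names(X))
    cnt <- rep(0L, nrow(X))
    for (ch in kids)
      cnt <- cnt + as.integer(X[[ch]] %in% spec$nodes[[ch]]$active_states)
    X[[v]] <- c("none", "one", "multi")[pmin(cnt, 2L) + 1L]
  }
  X
}

#' Discretize a continuous column into quantile bins
#'
#' @param x numeric vector.
#' @param bins number of quantile bins (default 3).
#' @return character vector of bin labels `q1..qN`.
#' @export
discretize_quantile <- function(x, bins = 3) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               na.rm = TRUE))
  if (length(br) < 2) return(rep("q1", length(x)))
  as.character(cut(x, br, include.lowest = TRUE,
                   labels = paste0("q", seq_len(length(br) - 1))))
}

#' Replace missing nominal values with an explicit state
#'
#' Keeps the network fully discrete in the presence of missingness: absent
#' nominal observations become the explicit state `"unknown"`.
#'
#' @param X data frame.
#' @param cols columns to treat (default: all non-numeric columns).
#' @return `X` with `NA`s replaced.
#' @export
impute_nominal_unknown <- function(X, cols = NULL) {
  if (is.null(cols))
    cols <- names(X)[!vapply(X, is.numeric, logical(1))]
  for (cn in cols) X[[cn]][is.na(X[[cn]])] <- "unknown"
  X
}

#' Mixed-type SMOTE class balancing
#'
#' Oversamples the minority class by interpolating between a minority row
#' and one of its `k` nearest minority neighbours, handling nominal and
#' continuous features jointly: continuous features are interpolated with a
#' uniform weight along the segment, nominal features are set by majority
#' vote among the `k` neighbours (ties broken by the seeded random stream).
#' Distances are Euclidean on standardized continuous features plus a
#' per-mismatch nominal penalty equal to the median standard deviation of
#' the (standardized) continuous features, ie 1. Original rows are never
#' altered or removed; synthetic rows are appended until the
#' minority/majority ratio reaches `target_ratio`.
#'
#' @param X data frame of features plus a binary label column.
#' @param k number of minority neighbours (default 5); the minority class
#'   must have more than `k` members.
#' @param target_ratio desired minority/majority row ratio (default 1).
#' @param seed integer seed.
#' @param label_col name of the label column (default `fall_next_hour`).
#' @param ignore columns excluded from distances and interpolation but
#'   carried through (eg `stay_id`); synthetic rows get `NA` there.
#' @return `X` with synthetic minority rows appended; attribute
#'   `"n_original"` gives the original row count.
#' @export
smote_balance <- function(X, k = 5, target_ratio = 1, seed = 1,
                          label_col = "fall_next_hour",
                          ignore = "stay_id") {
  stopifnot(label_col %in% names(X), k >= 1)
  lab <- X[[label_col]]
  classes <- sort(unique(lab))
  if (length(classes) != 2) stop("label must be binary with both classes present")
  n_by <- table(lab)
  minority <- names(n_by)[which.min(n_by)]
  m <- as.integer(min(n_by)); n_major <- as.integer(max(n_by))
  if (m <= k)
    stop("minority class has ", m, " rows; needs more than k = ", k)
  n_syn <- max(0L, as.integer(ceiling(target_ratio * n_major - m)))
  if (n_syn == 0L) { attr(X, "n_original") <- nrow(X); return(X) }

  ignore <- intersect(ignore, names(X))
  feat_cols <- setdiff(names(X), c(label_col, ignore))
  is_cont <- vapply(X[feat_cols], is.numeric, logical(1))
  cont <- feat_cols[is_cont]; nom <- feat_cols[!is_cont]

  Mi <- which(lab == minority)
  Z <- NULL
  if (length(cont)) {
    Z <- scale(as.matrix(X[cont]))   # unit-SD continuous features
    Z[!is.finite(Z)] <- 0
  }
  penalty <- 1  # median SD of standardized continuous features

  # pairwise distances among minority rows only
  d2 <- matrix(0, m, m)
  if (length(cont)) {
    Zm <- Z[Mi, , drop = FALSE]
    d2 <- as.matrix(stats::dist(Zm))^2
  }
  if (length(nom)) {
    for (cn in nom) {
      v <- X[[cn]][Mi]
      d2 <- d2 + penalty^2 * outer(v, v, FUN = "!=")
    }
  }
  diag(d2) <- Inf
  nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))  # m x k neighbour idx

  set.seed(child_seed(seed, 7))
  base <- ((seq_len(n_syn) - 1L) %% m) + 1L
  pick <- nn[cbind(base, sample.int(k, n_syn, replace = TRUE))]
  gap <- stats::runif(n_syn)

  syn <- X[Mi[base], , drop = FALSE]
  if (length(cont)) {
    A <- as.matrix(X[Mi[base], cont, drop = FALSE])
    B <- as.matrix(X[Mi[pick], cont, drop = FALSE])
    syn[cont] <- A + gap * (B - A)
  }
  if (length(nom)) {
    for (cn in nom) {
      vals <- X[[cn]][Mi]
      votes <- matrix(vals[t(nn)], nrow = k)      # k x m, votes per base row
      assigned <- character(m); tied <- vector("list", m)
      for (i in seq_len(m)) {
        tab <- table(votes[, i])
        win <- names(tab)[tab == max(tab)]
        if (length(win) == 1L) assigned[i] <- win else tied[[i]] <- win
      }
      out <- assigned[base]
      tie_rows <- which(out == "")
      if (length(tie_rows)) {
        out[tie_rows] <- vapply(tie_rows, function(j)
          sample(tied[[base[j]]], 1L), "")
      }
      syn[[cn]] <- out
    }
  }
  for (cn in ignore) syn[[cn]] <- NA
  syn[[label_col]] <- minority
  rownames(syn) <- NULL
  out <- rbind(X, syn)
  rownames(out) <- NULL
  attr(out, "schema") <- attr(X, "schema")
  attr(out, "n_original") <- nrow(X)
  out
}

#' Stratified train/validation split
#'
#' Splits rows 7:3 (by default) preserving the class balance to within one
#' row per class. With `group_col` set, whole groups (eg stays) are assigned
#' to one side, stratifying groups by whether they contain any positive row,
#' which prevents within-stay leakage between the splits.
#'
#' @param X data frame with a binary label column.
#' @param train_fraction fraction assigned to training (default 0.7).
#' @param seed integer seed.
#' @param label_col label column name.
#' @param group_col optional grouping column kept intact across the split.
#' @return list with `train` and `valid` data frames.
#' @export
stratified_split <- function(X, train_fraction = 0.7, seed = 1,
                             label_col = "fall_next_hour", group_col = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  lab <- X[[label_col]]
  if (length(unique(lab)) < 2)
    stop("both classes must be present to split")
  set.seed(child_seed(seed, 11))
  if (is.null(group_col)) {
    tr <- logical(nrow(X))
    for (cl in unique(lab)) {
      i <- which(lab == cl)
      tr[sample(i, round(train_fraction * length(i)))] <- TRUE
    }
  } else {
    g <- X[[group_col]]
    pos_lv <- sort(unique(lab))[2]
    g_pos <- unique(g[lab == pos_lv])
    g_all <- unique(g)
    tr_g <- character(0)
    for (set_g in list(g_pos, setdiff(g_all, g_pos))) {
      if (!length(set_g)) next
      tr_g <- c(tr_g, sample(set_g, round(train_fraction * length(set_g))))
    }
    tr <- g %in% tr_g
  }
  out <- list(train = X[tr, , drop = FALSE], valid = X[!tr, , drop = FALSE])
  for (nm in names(out)) {
    rownames(out[[nm]]) <- NULL
    attr(out[[nm]], "schema") <- attr(X, "schema")
  }
  out
}
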