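#' Confusion-matrix metrics at a threshold
#'
#' A prediction is positive when `score >= threshold` (ties at the threshold
#' count as positive, so results are bit-stable).
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (logical, 0/1, or a two-level factor/character
#'   whose larger level is the positive class).
#' @param threshold operating threshold.
#' @param variant optional label recorded in the report (eg
#'   `"with_heuristic"`).
#' @return list of class `fp_eval` with `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `auroc`, `threshold`, `n_pos`, `n_neg`, `tp`, `fp`, `tn`, `fn`,
#'   `variant`.
#' @export
confusion_metrics <- function(scores, labels, threshold, variant = NA_character_) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2)
    stop("degenerate input: both classes must be present")
  pred <- scores >= threshold
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
  fn <- sum(!pred & y == 1); tn <- sum(!pred & y == 0)
  structure(list(
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    auroc = auroc(scores, y), threshold = threshold,
    n_pos = tp + fn, n_neg = tn + fp,
    tp = tp, fp = fp, tn = tn, fn = fn, variant = variant),
    class = "fp_eval")
}

#' @export
print.fp_eval <- function(x, ...) {
  cat(sprintf(
    "Evaluation%s: sens %.4f  spec %.4f  ppv %.4f  npv %.4f  AUROC %.4f (threshold %.4g; %d pos / %d neg)\n",
    if (is.na(x$variant)) "" else paste0(" [", x$variant, "]"),
    x$sensitivity, x$specificity, x$ppv, x$npv, x$auroc, x$threshold,
    x$n_pos, x$n_neg))
  invisible(x)
}

as_binary_label <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  u <- sort(unique(as.character(labels)))
  if (length(u) > 2) stop("labels must be binary")
  as.integer(as.character(labels) == u[length(u)])
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic: the proportion of
#' (positive, negative) pairs in which the positive scores higher, counting
#' ties as half. This equals the trapezoidal area under the empirical ROC
#' curve.
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (see [confusion_metrics()]).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as_binary_label(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("degenerate input: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Points of the empirical ROC curve
#'
#' @param scores,labels as in [auroc()].
#' @return data frame with `threshold`, `fpr`, `tpr`, ordered from the
#'   all-negative to the all-positive corner.
#' @export
roc_points <- function(scores, labels) {
  y <- as_binary_label(labels)
  s <- sort(unique(scores), decreasing = TRUE)
  idx <- match(scores, s)
  tp <- cumsum(tabulate(idx[y == 1], length(s)))
  fp <- cumsum(tabulate(idx[y == 0], length(s)))
  data.frame(threshold = c(Inf, s),
             fpr = c(0, fp / sum(y == 0)),
             tpr = c(0, tp / sum(y == 1)))
}

#' Select an operating threshold by Youden's J
#'
#' Scans the midpoints between adjacent distinct scores (plus the two outer
#' extremes) and returns the threshold maximising J = sensitivity +
#' specificity - 1; ties resolve to the lowest threshold. On perfectly
#' separable data this is the midpoint of the separating gap.
#'
#' @param scores,labels as in [auroc()].
#' @param method only `"youden"` is implemented.
#' @return the selected threshold.
#' @export
threshold_select <- function(scores, labels, method = "youden") {
  method <- match.arg(method)
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2)
    stop("degenerate input: both classes must be present")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  s <- sort(unique(scores))
  cand <- if (length(s) == 1) s else
    c(s[1] - 1, (s[-length(s)] + s[-1]) / 2, s[length(s)] + 1)
  # cumulative counts below each candidate give sens/spec in one pass
  idx <- match(scores, s)
  pos_below <- c(0, cumsum(tabulate(idx[y == 1], length(s))))
  neg_below <- c(0, cumsum(tabulate(idx[y == 0], length(s))))
  cut_idx <- c(0, seq_along(s))         # candidates sit between distinct scores
  sens <- (n1 - pos_below[cut_idx + 1]) / n1
  spec <- neg_below[cut_idx + 1] / n0
  j <- sens + spec - 1
  cand[which.max(j)]  # which.max takes the first, ie lowest, on ties
}
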