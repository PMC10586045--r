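#' Fall rate per 1000 hospital-days
#'
#' @param falls number of falls.
#' @param hospital_days hospital-days denominator (> 0).
#' @param digits decimals reported (half-up; default 2).
#' @return `1000 * falls / hospital_days`, rounded.
#' @export
falls_per_1000 <- function(falls, hospital_days, digits = 2) {
  if (any(hospital_days <= 0)) stop("hospital_days must be positive")
  round_half_up(1000 * falls / hospital_days, digits)
}

# Newey-West HAC covariance with Bartlett weights w_l = 1 - l/(L+1) and the
# small-sample scaling n/(n-k) used by common econometrics software.
newey_west_vcov <- function(X, resid, lag) {
  n <- nrow(X); k <- ncol(X)
  Xe <- X * resid
  S <- crossprod(Xe)
  if (lag > 0) {
    for (l in seq_len(lag)) {
      w <- 1 - l / (lag + 1)
      G <- crossprod(Xe[(l + 1):n, , drop = FALSE], Xe[1:(n - l), , drop = FALSE])
      S <- S + w * (G + t(G))
    }
  }
  S <- S * n / (n - k)
  XtXinv <- solve(crossprod(X))
  XtXinv %*% S %*% XtXinv
}

itsa_summarise <- function(X, y, lag, terms) {
  n <- nrow(X); k <- ncol(X)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  V <- newey_west_vcov(X, fit$residuals, lag)
  se <- sqrt(diag(V))
  tval <- beta / se
  df <- n - k
  p <- 2 * stats::pt(-abs(tval), df)
  q <- stats::qt(0.975, df)
  structure(list(
    coefficients = data.frame(term = terms, estimate = as.numeric(beta),
                              hac_se = as.numeric(se), t = as.numeric(tval),
                              p = as.numeric(p),
                              ci_low = as.numeric(beta - q * se),
                              ci_high = as.numeric(beta + q * se),
                              row.names = NULL, stringsAsFactors = FALSE),
    lag = lag, n_obs = n, df = df, residuals = as.numeric(fit$residuals),
    vcov = V), class = "fp_itsa")
}

#' @export
print.fp_itsa <- function(x, ...) {
  cat("Interrupted time-series fit (Newey-West SE, lag", x$lag, ",",
      x$n_obs, "obs)\n")
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Single-group interrupted time-series regression
#'
#' Segmented OLS regression of the monthly fall rate,
#' `y = b0 + b1*t + b2*D + b3*(t - t0)*D`, where `t` runs 1..n, `D` switches
#' on at the intervention month `t0` (inclusive, so `b2` is the immediate
#' level change in the first intervention month) and `(t - t0)*D` starts at
#' 0 there (so `b3` is the change in monthly trend). Standard errors are
#' heteroskedasticity- and autocorrelation-consistent (Newey-West, Bartlett
#' weights) with the given lag; p-values and 95% CIs use the t distribution
#' with `n - k` degrees of freedom.
#'
#' @param series data frame with columns `month` (ordered index) and `rate`
#'   (falls per 1000 hospital-days), eg one group of
#'   [generate_its_panel()].
#' @param intervention_month first month (value of `series$month`) with the
#'   intervention in place; at least 3 observations are required on each
#'   side.
#' @param lag Newey-West lag (default 1).
#' @return an `fp_itsa` object; terms are `level`, `trend`, `level_change`,
#'   `trend_change`.
#' @export
fit_itsa <- function(series, intervention_month, lag = 1) {
  series <- series[order(series$month), ]
  t <- as.numeric(series$month)
  y <- as.numeric(series$rate)
  D <- as.numeric(t >= intervention_month)
  if (sum(D == 0) < 3 || sum(D == 1) < 3)
    stop("need at least 3 pre- and 3 post-intervention observations")
  X <- cbind(1, t, D, (t - intervention_month) * D)
  colnames(X) <- c("level", "trend", "level_change", "trend_change")
  itsa_summarise(X, y, lag, colnames(X))
}

#' Two-group interrupted time-series regression
#'
#' Pools two aligned monthly series and adds a group indicator `z` with full
#' interactions, estimating, on top of the reference group's four segmented
#' terms, the between-group differences in baseline level, baseline trend,
#' immediate level change and trend change. HAC errors as in [fit_itsa()].
#'
#' @param series data frame with columns `group` (exactly 2 levels), `month`,
#'   `rate`; both groups must cover the same months.
#' @param intervention_month,lag as in [fit_itsa()].
#' @param reference group treated as reference (`z = 0`); default the first
#'   group in sort order.
#' @return an `fp_itsa`; difference terms are prefixed `group_`.
#' @export
fit_multigroup_itsa <- function(series, intervention_month, lag = 1,
                                reference = NULL) {
  gs <- sort(unique(series$group))
  if (length(gs) != 2) stop("exactly 2 groups are required")
  reference <- reference %||% gs[1]
  if (!reference %in% gs) stop("reference group not present")
  other <- setdiff(gs, reference)
  m1 <- sort(series$month[series$group == reference])
  m2 <- sort(series$month[series$group == other])
  if (!identical(as.numeric(m1), as.numeric(m2)))
    stop("months must be aligned across groups")
  series <- series[order(series$group != reference, series$month), ]
  t <- as.numeric(series$month)
  y <- as.numeric(series$rate)
  z <- as.numeric(series$group == other)
  D <- as.numeric(t >= intervention_month)
  if (sum(D[z == 0] == 0) < 3 || sum(D[z == 0] == 1) < 3)
    stop("need at least 3 pre- and 3 post-intervention observations")
  td <- (t - intervention_month) * D
  X <- cbind(1, t, D, td, z, z * t, z * D, z * td)
  colnames(X) <- c("level", "trend", "level_change", "trend_change",
                   "group_level_diff", "group_trend_diff",
                   "group_level_change_diff", "group_trend_change_diff")
  itsa_summarise(X, y, lag, colnames(X))
}

#' Aggregate falls and hospital-days to monthly rates
#'
#' @param falls data frame with `event_time` (POSIXct) and optionally
#'   `group`.
#' @param hospital_days data frame with `month` (`"YYYY-MM"`), `group`,
#'   `hospital_days`.
#' @return data frame `group`, `month` (index), `falls`, `hospital_days`,
#'   `rate`.
#' @export
monthly_series <- function(falls, hospital_days) {
  fm <- format(falls$event_time, "%Y-%m")
  g <- if ("group" %in% names(falls)) falls$group else "all"
  cnt <- as.data.frame(table(group = g, month = fm), stringsAsFactors = FALSE)
  out <- merge(hospital_days, cnt, by = c("group", "month"), all.x = TRUE)
  out$Freq[is.na(out$Freq)] <- 0
  out <- out[order(out$group, out$month), ]
  data.frame(group = out$group,
             month = as.integer(factor(out$month, levels = sort(unique(out$month)))),
             falls = out$Freq, hospital_days = out$hospital_days,
             rate = 1000 * out$Freq / out$hospital_days,
             stringsAsFactors = FALSE)
}
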