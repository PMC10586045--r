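#' Site profiles for the packaged four-hospital study setting
#'
#' Encodes the study-setting profile of each hospital: the heuristic bedside
#' fall-risk tool in local use, the number of locally mapped high-risk drug
#' classes, whether nursing-needs classification (KPCS) data are recorded,
#' the admission volume and fall rate the generator is calibrated to, and
#' which mapping fixture restricts the site's recordable vocabulary.
#'
#' @param path YAML profile file; defaults to the packaged profiles.
#' @return data frame with one row per site, of class `fp_site_profiles`.
#' @export
site_profiles <- function(path = NULL) {
  path <- path %||% system.file("extdata", "site_profiles.yaml", package = "fallcds")
  raw <- yaml::read_yaml(path)
  rows <- lapply(raw$sites, function(s) {
    stopifnot(!is.null(s$site_id), !is.null(s$target_fall_rate))
    if (s$target_fall_rate <= 0) stop("target_fall_rate must be positive")
    data.frame(site_id = s$site_id,
               heuristic_tool = match.arg(s$heuristic_tool,
                                          c("morse", "hendrich2", "stratify")),
               n_drug_classes = as.integer(s$n_drug_classes),
               kpcs_available = isTRUE(s$kpcs_available),
               target_fall_rate = s$target_fall_rate,
               n_admissions = as.integer(s$n_admissions),
               mean_los_days = s$mean_los_days,
               coverage_fixture = s$coverage_fixture,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fp_site_profiles", class(out))
  out
}

#' Default per-risk-category effect sizes for the generator
#'
#' Odds multipliers applied to the hourly fall hazard per active finding in
#' each risk-factor category, plus `protection`, the multiplier for an
#' active preventive nursing intervention. Setting every entry to 1 yields a
#' cohort in which falls are independent of all features.
#' @return named numeric vector.
#' @export
default_risk_effects <- function() {
  c(cognition = 3.5, mobility = 3.0, toileting = 2.0, medications = 2.0,
    sensory = 1.6, sleep = 1.6, protection = 0.7)
}

# noise (in latent-risk SD units) added to the heuristic tool score, chosen
# so the tool alone discriminates in the moderate 0.65-0.74 AUROC range
# typical of bedside scales, with the Morse scale the least noisy of the
# three (binormal calibration against the latent-risk separation).
heuristic_tool_noise <- function(tool) {
  switch(tool, morse = 2.6, hendrich2 = 3.2, stratify = 3.5,
         stop("unknown heuristic tool: ", tool))
}

#' Generate a synthetic single-site EMR cohort
#'
#' Emulates the data structure the fall-risk analysis consumes: inpatient
#' stays, hourly observations of discrete concept-model features, and fall
#' events. Each stay carries a latent frailty; feature prevalences load on
#' it, and the hourly fall hazard is a logistic function of the active
#' findings weighted by `risk_effects` (log-odds additive). The hazard
#' intercept is calibrated numerically so the expected fall rate over the
#' realized eligible observations equals the profile's target rate (events
#' per 1000 hospital-days). Heuristic tool scores are noisy monotone
#' transforms of the latent risk, banded low/med/high. A configurable
#' fraction of stays violates the eligibility criteria so downstream filters
#' are exercised.
#'
#' @param profile one row of [site_profiles()] (or an equivalent list).
#' @param n_stays number of stays to generate.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param risk_effects named odds multipliers, see [default_risk_effects()].
#' @param frac_ineligible fraction of stays violating the inclusion criteria.
#' @param vocabulary optional character vector of catalog statement ids the
#'   site can record (defaults to the intervention statements mapped at the
#'   site's coverage fixture).
#' @return an object of class `fp_cohort`: list with `profile`, `stays`,
#'   `observations`, `falls`, `calibration`.
#' @export
generate_site_cohort <- function(profile, n_stays, seed,
                                 risk_effects = default_risk_effects(),
                                 frac_ineligible = 0.05,
                                 vocabulary = NULL) {
  stopifnot(n_stays >= 1)
  profile <- as.list(profile)
  req <- c("cognition", "mobility", "toileting", "medications", "sensory",
           "sleep", "protection")
  if (!all(req %in% names(risk_effects)))
    stop("risk_effects must name: ", paste(req, collapse = ", "))
  lo <- log(risk_effects)

  set.seed(child_seed(seed, 1))
  origin <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")

  ## ---- stays ----------------------------------------------------------
  u <- stats::rnorm(n_stays)                       # latent frailty
  age <- pmin(95, pmax(18, round(62 + 11 * u + 9 * stats::rnorm(n_stays))))
  los_days <- pmax(1.1, stats::rlnorm(n_stays,
                                      log(profile$mean_los_days) - 0.5 * 0.6^2, 0.6))
  excluded_condition <- rep(NA_character_, n_stays)
  n_bad <- round(frac_ineligible * n_stays)
  if (n_bad > 0) {
    bad <- sample.int(n_stays, n_bad)
    kind <- sample(c("minor", "short", "condition"), n_bad, replace = TRUE)
    age[bad[kind == "minor"]] <- sample(5:17, sum(kind == "minor"), replace = TRUE)
    los_days[bad[kind == "short"]] <- stats::runif(sum(kind == "short"), 0.2, 0.9)
    excluded_condition[bad[kind == "condition"]] <-
      sample(c("psychiatric", "obstetric", "emergency", "pediatric"),
             sum(kind == "condition"), replace = TRUE)
  }
  los_hours <- pmax(1L, as.integer(floor(los_days * 24)))
  admit <- origin + stats::runif(n_stays, 0, 364 * 24) * 3600
  stays <- data.frame(
    stay_id = sprintf("%s-%05d", profile$site_id, seq_len(n_stays)),
    age = age,
    admit_time = admit,
    discharge_time = admit + los_hours * 3600,
    unit = sprintf("unit%02d", 1 + (seq_len(n_stays) %% 6)),
    excluded_condition = excluded_condition,
    prior_fall_history = stats::runif(n_stays) < stats::plogis(-2.2 + 0.8 * u),
    stringsAsFactors = FALSE)
  eligible <- stays$age >= 18 & los_hours >= 24 & is.na(excluded_condition)

  ## ---- per-stay features ----------------------------------------------
  kpcs <- isTRUE(profile$kpcs_available)
  ord3 <- function(latent, cuts) {
    cut(latent, breaks = c(-Inf, cuts, Inf),
        labels = c("independent", "assisted", "dependent"))
  }
  stay_feat <- list(
    age_band = as.character(cut(age, c(-Inf, 49.5, 69.5, Inf),
                                labels = c("a18_49", "a50_69", "a70_plus"))),
    prior_fall = ifelse(stays$prior_fall_history, "yes", "no"),
    sedative = ifelse(stats::runif(n_stays) < stats::plogis(-1.5 + 0.6 * u), "yes", "no"),
    diuretic = ifelse(stats::runif(n_stays) < stats::plogis(-1.6 + 0.4 * u), "yes", "no"),
    other_highrisk_med = ifelse(
      stats::runif(n_stays) <
        stats::plogis(-3.0 + 0.15 * profile$n_drug_classes + 0.5 * u), "yes", "no"))
  if (kpcs) {
    stay_feat$kpcs_transfer <- as.character(ord3(u + 0.8 * stats::rnorm(n_stays), c(0.8, 1.8)))
    stay_feat$kpcs_ambulation <- as.character(ord3(u + 0.8 * stats::rnorm(n_stays), c(0.6, 1.7)))
    stay_feat$kpcs_consciousness <- ifelse(
      stats::runif(n_stays) < stats::plogis(-2.4 + 1.2 * u), "confused", "alert")
  }

  ## ---- hourly observations --------------------------------------------
  set.seed(child_seed(seed, 2))
  H <- sum(los_hours)
  idx <- rep(seq_len(n_stays), los_hours)              # stay index per row
  uu <- u[idx]
  hour_index <- sequence(los_hours) - 1L
  hourly <- function(a, b) stats::runif(H) < stats::plogis(a + b * uu)
  obs <- data.frame(stay_id = stays$stay_id[idx], hour_index = hour_index,
                    stringsAsFactors = FALSE)
  for (nm in names(stay_feat)) obs[[nm]] <- stay_feat[[nm]][idx]
  obs$impaired_mobility <- ifelse(hourly(-1.8, 1.0), "yes", "no")
  obs$confusion_dx <- ifelse(hourly(-2.5, 1.2), "yes", "no")
  obs$toileting_urgency <- ifelse(hourly(-2.0, 0.6), "yes", "no")
  obs$sensory_deficit <- ifelse(hourly(-2.3, 0.5), "yes", "no")
  obs$sleep_disturbance <- ifelse(hourly(-2.0, 0.5), "yes", "no")
  obs$fall_precaution_active <- ifelse(hourly(-1.0, 0.8), "yes", "no")

  ## ---- hourly hazard ---------------------------------------------------
  w <- numeric(H)
  add <- function(w, active, weight, cat) w + weight * lo[[cat]] * active
  w <- add(w, obs$age_band == "a70_plus", 0.7, "mobility")
  w <- add(w, obs$age_band == "a50_69", 0.3, "mobility")
  w <- add(w, obs$prior_fall == "yes", 1.0, "mobility")
  if (kpcs) {
    w <- add(w, obs$kpcs_transfer == "assisted", 0.5, "mobility")
    w <- add(w, obs$kpcs_transfer == "dependent", 1.0, "mobility")
    w <- add(w, obs$kpcs_ambulation == "assisted", 0.5, "mobility")
    w <- add(w, obs$kpcs_ambulation == "dependent", 1.0, "mobility")
    w <- add(w, obs$kpcs_consciousness == "confused", 1.0, "cognition")
  }
  w <- add(w, obs$sedative == "yes", 1.0, "medications")
  w <- add(w, obs$diuretic == "yes", 0.7, "medications")
  w <- add(w, obs$other_highrisk_med == "yes", 0.5, "medications")
  w <- add(w, obs$impaired_mobility == "yes", 1.0, "mobility")
  w <- add(w, obs$confusion_dx == "yes", 1.0, "cognition")
  w <- add(w, obs$toileting_urgency == "yes", 1.0, "toileting")
  w <- add(w, obs$sensory_deficit == "yes", 1.0, "sensory")
  w <- add(w, obs$sleep_disturbance == "yes", 1.0, "sleep")
  risk_score <- w                                    # latent risk (pre-protection)
  w <- add(w, obs$fall_precaution_active == "yes", 1.0, "protection")

  target_hourly <- profile$target_fall_rate / 24000  # per-hour event probability
  el_rows <- eligible[idx]
  f_of <- function(b0) mean(stats::plogis(b0 + w[el_rows])) - target_hourly
  if (f_of(2) < 0)
    stop("calibration error: target fall rate ", profile$target_fall_rate,
         " per 1000 hospital-days is unreachable with these effect sizes")
  b0 <- stats::uniroot(f_of, c(-30, 2), tol = 1e-12)$root

  set.seed(child_seed(seed, 3))
  obs$fall_next_hour <- ifelse(stats::runif(H) < stats::plogis(b0 + w), "yes", "no")

  ## ---- heuristic tool score -------------------------------------------
  sd_s <- stats::sd(risk_score[el_rows])
  tool_sd <- heuristic_tool_noise(profile$heuristic_tool) * max(sd_s, 1e-12)
  score <- risk_score + stats::rnorm(H, 0, tool_sd)
  cuts <- stats::quantile(score, c(0.60, 0.85), names = FALSE)
  if (cuts[1] >= cuts[2]) cuts <- c(cuts[1], cuts[1] + 1e-9)
  obs$heuristic_band <- as.character(cut(score, c(-Inf, cuts, Inf),
                                         labels = c("low", "med", "high")))
  obs$heuristic_score <- score

  ## ---- recorded statements (site vocabulary constrained) --------------
  if (is.null(vocabulary)) {
    cat <- fp_catalog()
    map <- read_local_mapping(system.file("extdata", profile$coverage_fixture,
                                          package = "fallcds"),
                              site_id = profile$site_id, catalog = cat)
    interv <- cat$statements$id[
      cat$statements$care_element %in%
        cat$elements$care_element[cat$elements$category == "intervention"]]
    vocabulary <- intersect(map$pairs$catalog_statement_id, interv)
  }
  obs$recorded_statement <- ""
  if (length(vocabulary)) {
    rec <- obs$fall_precaution_active == "yes" & stats::runif(H) < 0.3
    obs$recorded_statement[rec] <- sample(vocabulary, sum(rec), replace = TRUE)
  }

  obs$age <- stays$age[idx]

  fell <- obs$fall_next_hour == "yes"
  falls <- data.frame(
    stay_id = obs$stay_id[fell],
    event_time = stays$admit_time[idx[fell]] + (obs$hour_index[fell] + 1L) * 3600,
    injury = stats::runif(sum(fell)) < 0.25,
    stringsAsFactors = FALSE)

  structure(list(profile = profile, stays = stays, observations = obs,
                 falls = falls,
                 calibration = list(intercept = b0,
                                    target_hourly = target_hourly,
                                    eligible_hours = sum(el_rows)),
                 seed = seed, vocabulary = vocabulary),
            class = "fp_cohort")
}

#' @export
print.fp_cohort <- function(x, ...) {
  cat("Synthetic cohort for site", x$profile$site_id, "-", nrow(x$stays),
      "stays,", nrow(x$observations), "hourly observations,",
      nrow(x$falls), "falls\n")
  invisible(x)
}

#' Realized fall rate of a cohort
#'
#' @param cohort an `fp_cohort`.
#' @param eligible_only count only stays meeting the eligibility criteria
#'   (the calibration population).
#' @return falls per 1000 hospital-days (unrounded).
#' @export
cohort_fall_rate <- function(cohort, eligible_only = TRUE) {
  keep <- if (eligible_only) {
    filt <- apply_inclusion_exclusion(cohort$stays)
    cohort$observations$stay_id %in% filt$kept$stay_id
  } else rep(TRUE, nrow(cohort$observations))
  hours <- sum(keep)
  falls <- sum(cohort$observations$fall_next_hour[keep] == "yes")
  1000 * falls / (hours / 24)
}

#' Generate per-group monthly fall-rate panels
#'
#' Draws one monthly series per group from a segmented-regression mean (level
#' and slope change at the intervention month) plus stationary AR(1) noise,
#' then converts rates to integer monthly fall counts over the specified
#' hospital-days denominator (so `rate = 1000 * falls / hospital_days` holds
#' exactly in the returned panel).
#'
#' @param spec_by_group named list of series specifications; each a list with
#'   `n_months`, `intervention_month`, `baseline_level`, `baseline_slope`,
#'   `level_change`, `slope_change`, `noise_sd` (innovation SD), `ar1_coeff`,
#'   `monthly_hospital_days`.
#' @param seed integer seed.
#' @return data frame with columns `group`, `month`, `falls`,
#'   `hospital_days`, `rate`.
#' @export
generate_its_panel <- function(spec_by_group, seed = 1) {
  nm <- vapply(spec_by_group, function(s) s$n_months, 0)
  if (length(unique(nm)) != 1) stop("all groups must share n_months")
  out <- list()
  for (gi in seq_along(spec_by_group)) {
    s <- spec_by_group[[gi]]
    if (s$intervention_month < 1 || s$intervention_month > s$n_months)
      stop("intervention_month must lie within 1..n_months")
    if (abs(s$ar1_coeff) >= 1) stop("ar1_coeff must lie in (-1, 1)")
    set.seed(child_seed(seed, 100 + gi))
    t <- seq_len(s$n_months)
    D <- as.numeric(t >= s$intervention_month)
    mu <- s$baseline_level + s$baseline_slope * t + s$level_change * D +
      s$slope_change * (t - s$intervention_month) * D
    e <- numeric(s$n_months)
    if (s$noise_sd > 0) {
      e[1] <- stats::rnorm(1, 0, s$noise_sd / sqrt(1 - s$ar1_coeff^2))
      for (i in seq_len(s$n_months - 1))
        e[i + 1] <- s$ar1_coeff * e[i] + stats::rnorm(1, 0, s$noise_sd)
    }
    rate <- pmax(0, mu + e)
    falls <- pmax(0L, as.integer(round(rate * s$monthly_hospital_days / 1000)))
    out[[gi]] <- data.frame(group = names(spec_by_group)[gi] %||% as.character(gi),
                            month = t, falls = falls,
                            hospital_days = s$monthly_hospital_days,
                            rate = 1000 * falls / s$monthly_hospital_days,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
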