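#' Load and validate a pipeline run configuration
#'
#' @param path YAML config (see the packaged `demo_config.yaml`): a `seed`,
#'   a `multisite` block (site ids, `n_stays`, `smote`, `split`, `alpha`)
#'   and a `longitudinal` block (series specs per group).
#' @return validated config list of class `fp_run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$seed <- cfg$seed %||% 1L
  ms <- cfg$multisite %||% list()
  ms$sites <- ms$sites %||% c("A", "B", "C", "D")
  ms$n_stays <- ms$n_stays %||% 800L
  ms$alpha <- ms$alpha %||% 1
  ms$smote <- utils::modifyList(list(k = 3, target_ratio = 1.0), ms$smote %||% list())
  ms$split <- utils::modifyList(list(train_fraction = 0.7), ms$split %||% list())
  cfg$multisite <- ms
  for (p in c(cfg$network_spec, cfg$rules)) {
    if (!is.null(p) && !file.exists(p)) stop("configured path does not exist: ", p)
  }
  class(cfg) <- "fp_run_config"
  cfg
}

# run a pipeline stage, aborting with the stage name and site context
with_stage <- function(stage, site, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", stage, " [site ", site, "]: ", conditionMessage(e),
         call. = FALSE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the multisite modelling study
#'
#' For every configured site: computes the catalog coverage table, generates
#' a synthetic cohort at the site's profile, filters and splits it by stay,
#' balances the training windows with SMOTE, fits the fall-risk network with
#' and without the heuristic-tool construct, evaluates both variants plus
#' the heuristic score alone on the untouched validation windows (threshold
#' by Youden's J), and computes the construct variance-reduction profile.
#' Writes per-site and cross-site tables plus a manifest (seeds and file
#' digests) under `out_dir`.
#'
#' @param config an `fp_run_config` (or path to one).
#' @param out_dir output directory, created if needed.
#' @param seed overrides the config seed when given.
#' @return invisibly, a list with per-site results and the cross-site
#'   comparison data frame.
#' @export
run_multisite <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- load_run_config(config)
  seed <- seed %||% config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  catalog <- fp_catalog()
  spec0 <- if (is.null(config$network_spec)) fp_network_spec() else
    build_network(config$network_spec)
  profiles <- site_profiles()
  ms <- config$multisite
  results <- list()
  comparison <- list()
  written <- character(0)

  for (site in ms$sites) {
    prof <- profiles[profiles$site_id == site, ]
    if (nrow(prof) != 1) stop("stage coverage [site ", site, "]: unknown site id")
    site_seed <- child_seed(seed, match(site, c("A", "B", "C", "D")))

    mapping <- fp_site_mapping(site)
    cov <- with_stage("coverage", site, coverage_table(catalog, mapping))
    written <- c(written, write_tsv(cov, file.path(out_dir,
                                                   sprintf("coverage_%s.tsv", site))))

    spec <- spec0
    if (!prof$kpcs_available) spec <- ablate_construct(spec, "kpcs")
    cohort <- with_stage("simulate", site,
                         generate_site_cohort(prof, ms$n_stays, site_seed))
    X <- build_feature_matrix(cohort, spec)
    split <- with_stage("split", site,
                        stratified_split(X, ms$split$train_fraction, site_seed,
                                         group_col = "stay_id"))
    train <- with_stage("smote", site,
                        smote_balance(split$train, k = ms$smote$k,
                                      target_ratio = ms$smote$target_ratio,
                                      seed = site_seed))
    # leakage guard: the validation windows are never resampled
    stopifnot(nrow(split$valid) ==
                sum(X$stay_id %in% split$valid$stay_id))
    train <- derive_construct_summaries(train, spec)
    valid <- derive_construct_summaries(split$valid, spec)

    net_full <- with_stage("train", site, fit_parameters(spec, train, ms$alpha))
    spec_wo <- ablate_construct(spec, "heuristic_tool")
    net_wo <- fit_parameters(spec_wo, train, ms$alpha)

    y <- valid$fall_next_hour
    s_full <- predict_risk(net_full, valid)
    s_wo <- predict_risk(net_wo, valid)
    heur_score <- valid$heuristic_score
    ev <- list(
      with_heuristic = confusion_metrics(s_full, y, threshold_select(s_full, y),
                                         variant = "with_heuristic"),
      without_heuristic = confusion_metrics(s_wo, y, threshold_select(s_wo, y),
                                            variant = "without_heuristic"),
      heuristic_only = confusion_metrics(heur_score, y,
                                         threshold_select(heur_score, y),
                                         variant = "heuristic_only"))
    vr <- vr_profile(net_full)
    written <- c(written,
                 write_tsv(eval_table(ev), file.path(out_dir, sprintf("eval_%s.tsv", site))),
                 write_tsv(vr, file.path(out_dir, sprintf("vr_%s.tsv", site))))
    results[[site]] <- list(coverage = cov, eval = ev, vr = vr,
                            seed = site_seed,
                            n_windows = nrow(X), n_falls = sum(X$fall_next_hour == "yes"))
    comparison[[site]] <- data.frame(
      site = site, coverage_percent = cov$percent[cov$care_element == "total"],
      auroc_with = ev$with_heuristic$auroc,
      auroc_without = ev$without_heuristic$auroc,
      auroc_heuristic_only = ev$heuristic_only$auroc,
      vr_share_heuristic = vr$share[vr$construct == "heuristic_tool"],
      stringsAsFactors = FALSE)
  }
  comparison <- do.call(rbind, comparison)
  rownames(comparison) <- NULL
  written <- c(written, write_tsv(comparison, file.path(out_dir, "comparison.tsv")))
  manifest <- data.frame(file = basename(written),
                         md5 = as.character(tools::md5sum(written)),
                         row.names = NULL, stringsAsFactors = FALSE)
  manifest <- rbind(data.frame(file = sprintf("(seed %d)", seed), md5 = ""),
                    manifest)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(sites = results, comparison = comparison, seed = seed))
}

eval_table <- function(ev) {
  do.call(rbind, lapply(ev, function(e)
    data.frame(variant = e$variant, sensitivity = e$sensitivity,
               specificity = e$specificity, ppv = e$ppv, npv = e$npv,
               auroc = e$auroc, threshold = e$threshold,
               n_pos = e$n_pos, n_neg = e$n_neg,
               row.names = NULL, stringsAsFactors = FALSE)))
}

#' Run the longitudinal outcome analysis
#'
#' Generates (or accepts) per-group monthly fall-rate panels, fits the
#' single-group interrupted time-series model per group and the pooled
#' two-group model, and emits coefficient tables plus a per-group monthly
#' mean nursing-activity table derived from a small cohort of the
#' longitudinal site.
#'
#' @param config an `fp_run_config` (or path); uses its `longitudinal`
#'   block.
#' @param out_dir output directory.
#' @param seed overrides the config seed.
#' @param panel optional pre-built panel (as from [generate_its_panel()]);
#'   generated from the config when omitted.
#' @return invisibly, list with `panel`, `fits` (per group), `multigroup`,
#'   `activity`.
#' @export
run_longitudinal <- function(config, out_dir, seed = NULL, panel = NULL) {
  if (is.character(config)) config <- load_run_config(config)
  seed <- seed %||% config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lg <- config$longitudinal
  if (is.null(lg)) stop("config has no longitudinal block")
  shared <- list(n_months = lg$n_months, intervention_month = lg$intervention_month,
                 monthly_hospital_days = lg$monthly_hospital_days)
  specs <- lapply(lg$groups, function(g) utils::modifyList(shared, g))
  if (is.null(panel)) panel <- generate_its_panel(specs, seed = child_seed(seed, 50))

  fits <- list()
  for (g in unique(panel$group)) {
    fits[[g]] <- fit_itsa(panel[panel$group == g, ], lg$intervention_month,
                          lag = lg$lag %||% 1)
    write_tsv(fits[[g]]$coefficients,
              file.path(out_dir, sprintf("itsa_%s.tsv", g)))
  }
  mg <- fit_multigroup_itsa(panel, lg$intervention_month, lag = lg$lag %||% 1)
  write_tsv(mg$coefficients, file.path(out_dir, "itsa_multigroup.tsv"))
  write_tsv(panel, file.path(out_dir, "monthly_panel.tsv"))

  # descriptive monthly nursing-activity means from a small cohort of the
  # longitudinal site, units split into the two historical groups
  prof <- site_profiles()
  prof <- prof[prof$site_id == (lg$site %||% "A"), ]
  cohort <- generate_site_cohort(prof, lg$activity_n_stays %||% 300,
                                 child_seed(seed, 51))
  obs <- cohort$observations
  stay_unit <- cohort$stays$unit[match(obs$stay_id, cohort$stays$stay_id)]
  grp <- ifelse(stay_unit %in% sprintf("unit%02d", 1:3), names(specs)[1],
                names(specs)[2] %||% names(specs)[1])
  mo <- format(cohort$stays$admit_time[match(obs$stay_id, cohort$stays$stay_id)] +
                 obs$hour_index * 3600, "%Y-%m")
  activity <- stats::aggregate(
    list(precaution_share = obs$fall_precaution_active == "yes",
         statement_share = nzchar(obs$recorded_statement)),
    by = list(group = grp, month = mo), FUN = mean)
  activity <- activity[order(activity$group, activity$month), ]
  rownames(activity) <- NULL
  write_tsv(activity, file.path(out_dir, "monthly_activity.tsv"))

  invisible(list(panel = panel, fits = fits, multigroup = mg,
                 activity = activity, seed = seed))
}

#' Packaged demonstration run configuration
#' @return path to the installed demo YAML config.
#' @export
fp_demo_config <- function() {
  system.file("extdata", "demo_config.yaml", package = "fallcds")
}
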