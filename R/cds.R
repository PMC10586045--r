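#' Load the tailored-recommendation rule table
#'
#' Rules connect predicted risk-factor categories (and, optionally,
#' medication classes) to catalog intervention statements. A rule fires when
#' all of its `risk_categories` are among the prediction's active categories
#' and all of its `med_classes` are among the patient's current medication
#' classes (conjunctive triggers). Every referenced statement must resolve
#' to an intervention-category catalog statement; violations are reported at
#' load, never at recommendation time. The packaged rule set seeds the two
#' worked clinical examples (impaired cognition; diuretic plus sedative use)
#' and one illustrative rule per remaining risk category.
#'
#' @param path YAML rule file; defaults to the packaged rules.
#' @param catalog an `fp_catalog` to validate against.
#' @return object of class `fp_rules`: list of rules, each with `id`,
#'   `risk_categories`, `med_classes`, `recommended`, `priority`.
#' @export
load_rules <- function(path = NULL, catalog = fp_catalog()) {
  path <- path %||% system.file("extdata", "cds_rules.yaml", package = "fallcds")
  raw <- yaml::read_yaml(path)
  interv_elems <- catalog$elements$care_element[catalog$elements$category == "intervention"]
  interv_ids <- catalog$statements$id[catalog$statements$care_element %in% interv_elems]
  rules <- lapply(raw$rules, function(r) {
    if (is.null(r$id) || is.null(r$recommended) || !length(r$recommended))
      stop("every rule needs an id and a nonempty recommended list")
    rec <- as.character(unlist(r$recommended))
    bad <- setdiff(rec, catalog$statements$id)
    if (length(bad))
      stop("rule '", r$id, "' references unknown statement(s): ",
           paste(bad, collapse = ", "))
    noniv <- setdiff(rec, interv_ids)
    if (length(noniv))
      stop("rule '", r$id, "' recommends non-intervention statement(s): ",
           paste(noniv, collapse = ", "))
    rc <- as.character(unlist(r$risk_categories %||% list()))
    bad_rc <- setdiff(rc, risk_category_levels())
    if (length(bad_rc))
      stop("rule '", r$id, "' has unknown risk category: ", bad_rc[1])
    list(id = r$id, risk_categories = rc,
         med_classes = as.character(unlist(r$med_classes %||% list())),
         recommended = rec, priority = as.integer(r$priority %||% 100L))
  })
  if (anyDuplicated(vapply(rules, `[[`, "", "id")))
    stop("duplicate rule id")
  structure(list(rules = rules,
                 universal = as.character(unlist(raw$universal %||% list()))),
            class = "fp_rules")
}

#' Recommend a tailored care plan
#'
#' Universal fall-prevention care is always included; each fired rule adds
#' its catalog statements, ordered by rule priority then rule id, with
#' duplicates removed. Adding risk factors or medication classes can only
#' add recommendations, never remove them.
#'
#' @param prediction result of [posterior_fall_risk()], or any list with an
#'   `active_risk_factors` data frame carrying a `risk_category` column.
#' @param meds character vector of current medication classes (eg
#'   `c("diuretic", "sedative")`).
#' @param rules an `fp_rules` object.
#' @param catalog the catalog the rules were validated against.
#' @return object of class `fp_care_plan`: list with `universal`, `tailored`
#'   (data frame `rule_id`, `statement_id`, `text`), `provenance` (fired rule
#'   ids).
#' @export
recommend <- function(prediction, meds = character(0), rules,
                      catalog = fp_catalog()) {
  active <- unique(unlist(lapply(
    prediction$active_risk_factors$risk_category, split_semi)))
  active <- active[!is.na(active)]
  fired <- Filter(function(r) {
    length(r$risk_categories) + length(r$med_classes) > 0 &&
      all(r$risk_categories %in% active) && all(r$med_classes %in% meds)
  }, rules$rules)
  ord <- order(vapply(fired, `[[`, 0L, "priority"),
               vapply(fired, `[[`, "", "id"))
  fired <- fired[ord]
  tailored <- do.call(rbind, lapply(fired, function(r)
    data.frame(rule_id = r$id, statement_id = r$recommended,
               stringsAsFactors = FALSE)))
  if (is.null(tailored))
    tailored <- data.frame(rule_id = character(0), statement_id = character(0),
                           stringsAsFactors = FALSE)
  tailored <- tailored[!duplicated(tailored$statement_id), , drop = FALSE]
  tailored <- tailored[!tailored$statement_id %in% rules$universal, , drop = FALSE]
  tailored$text <- catalog$statements$text[
    match(tailored$statement_id, catalog$statements$id)]
  rownames(tailored) <- NULL
  structure(list(universal = rules$universal, tailored = tailored,
                 provenance = vapply(fired, `[[`, "", "id")),
            class = "fp_care_plan")
}

#' @export
print.fp_care_plan <- function(x, ...) {
  cat("Care plan:", length(x$universal), "universal statement(s);",
      nrow(x$tailored), "tailored recommendation(s)\n")
  if (nrow(x$tailored))
    cat(paste0("  [", x$tailored$rule_id, "] ", x$tailored$statement_id, ": ",
               x$tailored$text, collapse = "\n"), "\n")
  invisible(x)
}
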