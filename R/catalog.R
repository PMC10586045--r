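#' Load a fall-prevention terminology catalog
#'
#' A catalog is the standard content model for inpatient fall prevention:
#' care elements (groupings such as universal care or alarm monitoring, split
#' into an assessment/diagnosis/outcome branch and an intervention branch),
#' the individual nursing statements under each element, and the risk-factor
#' categories attached to intervention statements. Statement-level texts in
#' the packaged fixture are synthetic placeholders; every computation in the
#' package depends only on the element/statement structure and counts.
#'
#' @param elements_path CSV with columns `care_element`, `category`
#'   (`assessment_diagnosis_outcome` or `intervention`), `n_statements`.
#' @param statements_path CSV with columns `id`, `care_element`, `text`,
#'   `risk_categories` (`;`-separated subset of the six risk categories,
#'   possibly empty).
#' @return an object of class `fp_catalog` with components `elements` and
#'   `statements` (data frames).
#' @seealso [fp_catalog()] for the packaged catalog, [coverage_table()].
#' @export
load_catalog <- function(elements_path, statements_path) {
  for (p in c(elements_path, statements_path))
    if (!file.exists(p)) stop("catalog file not found: ", p)
  el <- utils::read.csv(elements_path, stringsAsFactors = FALSE)
  st <- utils::read.csv(statements_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need_el <- c("care_element", "category", "n_statements")
  need_st <- c("id", "care_element", "text", "risk_categories")
  if (!all(need_el %in% names(el)))
    stop("element file is missing columns: ",
         paste(setdiff(need_el, names(el)), collapse = ", "))
  if (!all(need_st %in% names(st)))
    stop("statement file is missing columns: ",
         paste(setdiff(need_st, names(st)), collapse = ", "))
  if (nrow(el) == 0 || nrow(st) == 0) stop("catalog files must be non-empty")
  el$n_statements <- as.integer(el$n_statements)

  bad <- !el$category %in% c("assessment_diagnosis_outcome", "intervention")
  if (any(bad))
    stop("unknown category in element row(s): ",
         paste(el$care_element[bad], collapse = ", "))
  if (anyDuplicated(el$care_element))
    stop("duplicate care element: ",
         el$care_element[duplicated(el$care_element)][1])
  if (any(el$n_statements < 1))
    stop("care element with no statements: ",
         el$care_element[el$n_statements < 1][1])
  if (anyDuplicated(st$id))
    stop("duplicate statement id: ", st$id[duplicated(st$id)][1])
  orphan <- !st$care_element %in% el$care_element
  if (any(orphan))
    stop("statement references unknown care element: ", st$id[orphan][1])

  tab <- table(factor(st$care_element, levels = el$care_element))
  mismatch <- as.integer(tab) != el$n_statements
  if (any(mismatch))
    stop("statement count mismatch for element '",
         el$care_element[mismatch][1], "': declared ",
         el$n_statements[mismatch][1], ", found ",
         as.integer(tab)[mismatch][1])

  valid_rc <- risk_category_levels()
  rcs <- lapply(st$risk_categories, split_semi)
  bad_rc <- vapply(rcs, function(r) any(!r %in% valid_rc), logical(1))
  if (any(bad_rc))
    stop("invalid risk category on statement: ", st$id[bad_rc][1])

  structure(list(elements = el, statements = st), class = "fp_catalog")
}

#' The six intervention risk-factor categories
#' @return character vector of category names.
#' @export
risk_category_levels <- function() {
  c("cognition", "toileting", "mobility", "medications", "sensory", "sleep")
}

#' Packaged fall-prevention catalog
#'
#' 98 statements across 13 care-element rows (protocol provision is merged
#' into risk-targeted care, giving 13 rows for 14 care elements).
#' @return an `fp_catalog`.
#' @export
fp_catalog <- function() {
  load_catalog(system.file("extdata", "catalog_elements.csv", package = "fallcds"),
               system.file("extdata", "catalog_statements.csv", package = "fallcds"))
}

#' @export
print.fp_catalog <- function(x, ...) {
  cat("Fall-prevention catalog:", nrow(x$statements), "statements in",
      nrow(x$elements), "care-element rows\n")
  invisible(x)
}

#' Read a site's local-statement mapping
#'
#' Each row pairs a site-local nursing statement with the catalog statement it
#' was judged semantically equivalent to; rows with an empty
#' `catalog_statement_id` record local statements with no catalog counterpart.
#' Several local phrases may map to one catalog statement; coverage counts
#' catalog statements, so such duplicates collapse to a single mapped
#' statement.
#'
#' @param path CSV with columns `local_statement_id`, `catalog_statement_id`.
#' @param site_id site label; defaults to the file name.
#' @param catalog optional `fp_catalog` used to validate catalog ids.
#' @return an object of class `fp_mapping` with `site_id`, `pairs`
#'   (deduplicated on catalog id) and `unmapped_local`.
#' @export
read_local_mapping <- function(path, site_id = NULL, catalog = NULL) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("local_statement_id", "catalog_statement_id")
  if (!all(need %in% names(df)))
    stop("mapping file is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$catalog_statement_id[is.na(df$catalog_statement_id)] <- ""
  unmapped <- df$local_statement_id[!nzchar(df$catalog_statement_id)]
  pairs <- df[nzchar(df$catalog_statement_id), need]
  pairs <- pairs[!duplicated(pairs$catalog_statement_id), ]
  m <- structure(list(site_id = site_id %||% sub("\\.[^.]*$", "", basename(path)),
                      pairs = pairs, unmapped_local = unmapped),
                 class = "fp_mapping")
  if (!is.null(catalog)) validate_mapping(m, catalog)
  m
}

validate_mapping <- function(mapping, catalog) {
  unknown <- setdiff(mapping$pairs$catalog_statement_id, catalog$statements$id)
  if (length(unknown))
    stop("mapping for site '", mapping$site_id,
         "' references unknown catalog statement(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  invisible(mapping)
}

#' Packaged site mappings
#'
#' The four per-site mapping fixtures whose per-element mapped counts equal
#' the published coverage table.
#' @param site one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return an `fp_mapping`.
#' @export
fp_site_mapping <- function(site = c("A", "B", "C", "D")) {
  site <- match.arg(site)
  read_local_mapping(system.file("extdata",
                                 sprintf("mapping_site_%s.csv", site),
                                 package = "fallcds"),
                     site_id = site, catalog = fp_catalog())
}

#' Per-element catalog coverage of a site's local statements
#'
#' For each care element, counts how many of its catalog statements have at
#' least one semantically equivalent local statement at the site, and reports
#' the percentage (half-up, one decimal). The final row is the overall
#' coverage across all 98 statements.
#'
#' @param catalog an `fp_catalog`.
#' @param mapping an `fp_mapping` for one site.
#' @return data frame with columns `care_element`, `category`, `n_statements`,
#'   `n_mapped`, `percent`; the last row (`care_element == "total"`) is the
#'   overall summary.
#' @export
coverage_table <- function(catalog, mapping) {
  validate_mapping(mapping, catalog)
  el <- catalog$elements
  st <- catalog$statements
  mapped_ids <- unique(mapping$pairs$catalog_statement_id)
  hit <- st$id %in% mapped_ids
  n_mapped <- as.integer(tapply(hit, factor(st$care_element, levels = el$care_element), sum))
  out <- data.frame(care_element = el$care_element,
                    category = el$category,
                    n_statements = el$n_statements,
                    n_mapped = n_mapped,
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(care_element = "total", category = "all",
                               n_statements = sum(el$n_statements),
                               n_mapped = sum(n_mapped)))
  out$percent <- round_half_up(100 * out$n_mapped / out$n_statements, 1)
  out
}

#' Care elements under a coverage threshold
#'
#' @param catalog an `fp_catalog`.
#' @param mapping an `fp_mapping`.
#' @param threshold_percent elements with coverage strictly below this
#'   percentage are returned, sorted ascending by coverage.
#' @return subset of the coverage table rows (no overall row).
#' @export
coverage_gap <- function(catalog, mapping, threshold_percent) {
  stopifnot(is.numeric(threshold_percent), length(threshold_percent) == 1)
  if (threshold_percent < 0 || threshold_percent > 100)
    stop("threshold_percent must lie in [0, 100]")
  tab <- coverage_table(catalog, mapping)
  tab <- tab[tab$care_element != "total" & tab$percent < threshold_percent, ]
  tab <- tab[order(tab$percent, tab$care_element), ]
  rownames(tab) <- NULL
  tab
}

#' Write a coverage table as tab-separated text
#' @param tab result of [coverage_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
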