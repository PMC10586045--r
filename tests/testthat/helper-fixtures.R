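# fixtures built in code at test time

# printed per-site coverage matrix: mapped counts and percentages per care
# element (rows in catalog order) plus the overall row
printed_coverage <- function() {
  elements <- c("pathophysiological", "therapeutics", "cognitive_factors",
                "risk_behaviors", "communication_ability", "situational_factors",
                "physical_environment", "universal_care", "environmental_management",
                "risk_targeted_care", "education_provision", "information_sharing",
                "alarm_monitoring", "total")
  list(
    elements = elements,
    n_statements = c(19, 7, 10, 3, 1, 1, 1, 13, 11, 19, 6, 5, 2, 98),
    mapped = cbind(
      A = c(19, 0, 4, 0, 1, 1, 0, 10, 3, 7, 6, 1, 0, 52),
      B = c(10, 1, 5, 1, 1, 0, 0, 5, 9, 10, 4, 1, 0, 47),
      C = c(18, 6, 5, 1, 1, 0, 0, 13, 3, 10, 6, 2, 0, 65),
      D = c(19, 2, 10, 1, 1, 0, 0, 10, 11, 19, 6, 5, 1, 85)),
    percent = cbind(
      A = c(100, 0, 40, 0, 100, 100, 0, 76.9, 27.3, 36.8, 100, 20, 0, 53.1),
      B = c(52.6, 14.3, 50, 33.3, 100, 0, 0, 38.5, 81.8, 52.6, 66.7, 20, 0, 48.0),
      C = c(94.7, 85.7, 50, 33.3, 100, 0, 0, 100, 27.3, 52.6, 100, 40, 0, 66.3),
      D = c(100, 28.6, 100, 33.3, 100, 0, 0, 76.9, 100, 100, 100, 100, 50, 86.7)))
}

# write a small catalog (two elements, five statements) to temp files
toy_catalog_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  el <- data.frame(care_element = c("universal_care", "cognitive_factors"),
                   category = c("intervention", "assessment_diagnosis_outcome"),
                   n_statements = c(3, 2))
  st <- data.frame(id = c("U1", "U2", "U3", "C1", "C2"),
                   care_element = c(rep("universal_care", 3),
                                    rep("cognitive_factors", 2)),
                   text = paste("stmt", 1:5),
                   risk_categories = c("cognition", "", "", "", ""))
  ep <- file.path(dir, "elements.csv"); sp <- file.path(dir, "statements.csv")
  write.csv(el, ep, row.names = FALSE)
  write.csv(st, sp, row.names = FALSE)
  list(elements = ep, statements = sp, dir = dir)
}

write_mapping_file <- function(pairs,
                               dir = withr::local_tempdir(.local_envir = parent.frame()),
                               name = "map.csv") {
  p <- file.path(dir, name)
  write.csv(data.frame(local_statement_id = sprintf("L%d", seq_len(nrow(pairs))),
                       catalog_statement_id = pairs$catalog_statement_id),
            p, row.names = FALSE)
  p
}

# minimal three-node chain network spec: t -> a -> b, all binary
toy_spec3 <- function() {
  fallcds::build_network(list(
    nodes = list(
      list(name = "t", states = list("no", "yes"), construct = "target"),
      list(name = "a", states = list("lo", "hi"), construct = "c1"),
      list(name = "b", states = list("lo", "hi"), construct = "c2")),
    edges = list(list("t", "a"), list("a", "b"))))
}

# small stays table exercising every eligibility rule
toy_stays <- function() {
  t0 <- as.POSIXct("2019-03-01 08:00:00", tz = "UTC")
  data.frame(
    stay_id = sprintf("S%02d", 1:10),
    age = c(40, 17, 40, 40, 85, 70, 22, 64, 33, 51),
    admit_time = rep(t0, 10),
    discharge_time = t0 + c(100, 100, 23, 24, 48, 72, 30, 200, 96, 500) * 3600,
    unit = "unit01",
    excluded_condition = c(NA, NA, NA, NA, "psychiatric", NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}
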