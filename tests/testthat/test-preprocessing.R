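test_that("eligibility rules drop the right stays with ordered reasons", {
  stays <- toy_stays()
  res <- apply_inclusion_exclusion(stays)
  expect_equal(nrow(res$kept), 7)
  expect_setequal(res$dropped$stay_id, c("S02", "S03", "S05"))
  expect_equal(res$dropped$reason[res$dropped$stay_id == "S02"], "age")
  expect_equal(res$dropped$reason[res$dropped$stay_id == "S03"], "duration")
  expect_equal(res$dropped$reason[res$dropped$stay_id == "S05"], "condition")
  # the 24-h boundary is inclusive
  expect_true("S04" %in% res$kept$stay_id)

  # age is checked first: an underage psychiatric stay reports "age"
  stays2 <- stays
  stays2$excluded_condition[stays2$stay_id == "S02"] <- "pediatric"
  res2 <- apply_inclusion_exclusion(stays2)
  expect_equal(res2$dropped$reason[res2$dropped$stay_id == "S02"], "age")

  # missing age is its own reason
  stays3 <- stays
  stays3$age[stays3$stay_id == "S01"] <- NA
  res3 <- apply_inclusion_exclusion(stays3)
  expect_equal(res3$dropped$reason[res3$dropped$stay_id == "S01"], "missing_age")

  # kept set is invariant to row order
  perm <- sample(nrow(stays))
  res4 <- apply_inclusion_exclusion(stays[perm, ])
  expect_setequal(res4$kept$stay_id, res$kept$stay_id)
})

make_toy_matrix <- function(n_min = 10, n_maj = 100, seed = 1) {
  set.seed(seed)
  data.frame(
    x = c(rnorm(n_min, 3), rnorm(n_maj, 0)),
    y = c(rnorm(n_min, -1), rnorm(n_maj, 0)),
    col = sample(c("red", "blue", "green"), n_min + n_maj, replace = TRUE),
    fall_next_hour = c(rep("yes", n_min), rep("no", n_maj)),
    stringsAsFactors = FALSE)
}

test_that("SMOTE adds exactly the rows needed to reach the target ratio", {
  X <- make_toy_matrix()
  out <- smote_balance(X, k = 3, target_ratio = 1, seed = 5, ignore = character(0))
  expect_equal(nrow(out), 200)           # 90 synthetic rows added
  expect_equal(sum(out$fall_next_hour == "yes"), 100)
  # originals retained untouched, majority unchanged
  expect_equal(out[seq_len(nrow(X)), ], X, ignore_attr = TRUE)
  # half ratio
  out2 <- smote_balance(X, k = 3, target_ratio = 0.5, seed = 5,
                        ignore = character(0))
  expect_equal(sum(out2$fall_next_hour == "yes"), 50)
  # ratio already satisfied: no-op
  out3 <- smote_balance(X, k = 3, target_ratio = 0.05, seed = 5,
                        ignore = character(0))
  expect_equal(nrow(out3), nrow(X))
})

test_that("SMOTE interpolates on minority-neighbour segments", {
  X <- make_toy_matrix(n_min = 8, n_maj = 60, seed = 2)
  k <- 2
  out <- smote_balance(X, k = k, target_ratio = 1, seed = 9, ignore = character(0))
  syn <- out[(nrow(X) + 1):nrow(out), ]
  min_rows <- X[X$fall_next_hour == "yes", ]
  # each synthetic point must lie on a segment between one minority row and
  # one of its k nearest minority neighbours (checked against a direct
  # enumeration of all minority pairs)
  on_segment <- function(p, a, b) {
    ab <- c(b$x - a$x, b$y - a$y); ap <- c(p$x - a$x, p$y - a$y)
    cross <- ab[1] * ap[2] - ab[2] * ap[1]
    within <- all(p$x >= min(a$x, b$x) - 1e-9, p$x <= max(a$x, b$x) + 1e-9,
                  p$y >= min(a$y, b$y) - 1e-9, p$y <= max(a$y, b$y) + 1e-9)
    abs(cross) < 1e-9 && within
  }
  for (i in seq_len(nrow(syn))) {
    hit <- FALSE
    for (a in seq_len(nrow(min_rows))) for (b in seq_len(nrow(min_rows))) {
      if (a != b && on_segment(syn[i, ], min_rows[a, ], min_rows[b, ])) hit <- TRUE
    }
    expect_true(hit)
  }
  # nominal value must come from the minority class values
  expect_true(all(syn$col %in% unique(min_rows$col)))
})

test_that("SMOTE degenerate and error cases", {
  # identical minority rows: synthetic copies of them
  X <- data.frame(x = c(rep(1.5, 6), rnorm(40, 5)),
                  col = c(rep("red", 6), rep("blue", 40)),
                  fall_next_hour = c(rep("yes", 6), rep("no", 40)),
                  stringsAsFactors = FALSE)
  out <- smote_balance(X, k = 2, target_ratio = 0.5, seed = 1,
                       ignore = character(0))
  syn <- out[(nrow(X) + 1):nrow(out), ]
  expect_true(all(syn$x == 1.5))
  expect_true(all(syn$col == "red"))

  expect_error(smote_balance(X, k = 6, target_ratio = 1, seed = 1,
                             ignore = character(0)), "needs more than k")
  X1 <- X; X1$fall_next_hour <- "no"
  expect_error(smote_balance(X1, k = 2, seed = 1), "binary")
})

test_that("nominal-only SMOTE votes among the k nearest neighbours", {
  # minority rows engineered so the vote outcome is hand-checkable:
  # rows 1-3 identical ("a"), rows 4-5 are "b"; with k = 2 every base row's
  # two nearest neighbours share its own nominal cluster where possible
  X <- data.frame(
    x = c(0, 0.1, 0.2, 10, 10.1, rnorm(30, 5, 0.1)),
    col = c("a", "a", "a", "b", "b", rep("m", 30)),
    fall_next_hour = c(rep("yes", 5), rep("no", 30)),
    stringsAsFactors = FALSE)
  out <- smote_balance(X, k = 2, target_ratio = 0.5, seed = 3,
                       ignore = character(0))
  syn <- out[(nrow(X) + 1):nrow(out), ]
  # bases cycle 1..5; neighbours of rows 1-3 are the other two "a" rows,
  # neighbours of rows 4-5 are one "b" and one "a" row (tie broken seeded)
  base <- ((seq_len(nrow(syn)) - 1) %% 5) + 1
  expect_true(all(syn$col[base <= 3] == "a"))
  expect_true(all(syn$col[base >= 4] %in% c("a", "b")))
})

test_that("stratified split preserves class balance and reproducibility", {
  X <- make_toy_matrix(10, 90)
  sp <- stratified_split(X, 0.7, seed = 2)
  expect_equal(nrow(sp$train), 70)
  expect_equal(sum(sp$train$fall_next_hour == "yes"), 7)
  expect_equal(nrow(sp$valid), 30)
  expect_equal(nrow(sp$train) + nrow(sp$valid), nrow(X))

  sp2 <- stratified_split(X, 0.7, seed = 2)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(X, 0.7, seed = 3)
  expect_false(identical(sp$train, sp3$train))

  X1 <- X; X1$fall_next_hour <- "no"
  expect_error(stratified_split(X1, 0.7, 1), "both classes")
})

test_that("event fractions agree between splits across seeds", {
  X <- make_toy_matrix(12, 88)
  for (s in 1:50) {
    sp <- stratified_split(X, 0.7, seed = s)
    f_tr <- mean(sp$train$fall_next_hour == "yes")
    f_va <- mean(sp$valid$fall_next_hour == "yes")
    expect_lte(abs(f_tr - f_va), 1 / min(nrow(sp$train), nrow(sp$valid)) + 1e-12)
  }
})

test_that("group-wise split keeps stays intact", {
  X <- make_toy_matrix(10, 90)
  X$stay_id <- rep(sprintf("S%02d", 1:20), each = 5)
  sp <- stratified_split(X, 0.7, seed = 4, group_col = "stay_id")
  expect_length(intersect(unique(sp$train$stay_id), unique(sp$valid$stay_id)), 0)
})

test_that("feature matrix carries schema and derives summaries", {
  prof <- site_profiles()
  co <- generate_site_cohort(prof[prof$site_id == "B", ], 80, seed = 3)
  spec <- fp_network_spec()
  X <- build_feature_matrix(co, spec)
  sch <- attr(X, "schema")
  expect_true(all(c("column", "construct", "kind") %in% names(sch)))
  expect_equal(sch$kind[sch$column == "age"], "continuous")
  expect_false("admin_summary" %in% names(X))
  X2 <- derive_construct_summaries(X, spec)
  expect_true(all(c("admin_summary", "med_summary", "assess_summary") %in% names(X2)))
  expect_true(all(X2$admin_summary %in% c("none", "one", "multi")))
  # summary equals the banded count of active findings
  cnt <- (X$age_band == "a70_plus") + (X$prior_fall == "yes") +
    (X$kpcs_transfer != "independent") + (X$kpcs_ambulation != "independent") +
    (X$kpcs_consciousness == "confused")
  expect_equal(X2$admin_summary, c("none", "one", "multi")[pmin(cnt, 2) + 1])
})

test_that("missing nominal values become an explicit state", {
  X <- data.frame(a = c("x", NA, "y"), b = c(1, 2, NA))
  out <- impute_nominal_unknown(X)
  expect_equal(out$a, c("x", "unknown", "y"))
  expect_true(is.na(out$b[3]))  # continuous left alone
})

test_that("quantile discretization produces the requested bins", {
  x <- c(rep(1, 5), rep(10, 5), rep(100, 5))
  expect_setequal(unique(discretize_quantile(x, 3)), c("q1", "q2", "q3"))
  expect_equal(unique(discretize_quantile(rep(4, 10), 3)), "q1")
})
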