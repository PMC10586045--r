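test_that("the packaged network is a valid three-layer concept model", {
  spec <- fp_network_spec()
  expect_s3_class(spec, "fp_network_spec")
  expect_equal(spec$target, "fall_next_hour")
  expect_setequal(network_constructs(spec),
                  c("demographics_admin", "kpcs", "medication",
                    "nursing_intervention", "nursing_assessment_diagnosis",
                    "heuristic_tool"))
  # summary layer between target and multi-feature constructs
  expect_setequal(network_constructs(spec, roles = "summary"),
                  c("demographics_admin", "medication",
                    "nursing_assessment_diagnosis"))
})

test_that("network validation rejects malformed specs", {
  nodes <- list(
    list(name = "t", states = list("no", "yes"), construct = "target"),
    list(name = "a", states = list("l", "h"), construct = "c1"),
    list(name = "b", states = list("l", "h"), construct = "c1"))
  expect_error(build_network(list(nodes = nodes,
                                  edges = list(list("a", "b"), list("b", "a")))),
               "cycle")
  expect_error(build_network(list(nodes = nodes[-1],
                                  edges = list(list("a", "b")))),
               "target")
  nodes2 <- nodes; nodes2[[3]]$name <- "a"
  expect_error(build_network(list(nodes = nodes2, edges = list())), "duplicate")
  nodes3 <- nodes
  nodes3[[1]]$states <- list("no", "yes", "maybe")
  expect_error(build_network(list(nodes = nodes3, edges = list())), "binary")
  expect_error(build_network(list(nodes = nodes,
                                  edges = list(list("a", "zz")))),
               "unknown node")
})

test_that("CPT fitting matches closed-form counts", {
  spec1 <- build_network(list(
    nodes = list(list(name = "fall_next_hour", states = list("no", "yes"),
                      construct = "target")), edges = list()))
  d <- data.frame(fall_next_hour = c(rep("yes", 30), rep("no", 70)))
  net <- fit_parameters(spec1, d, alpha = 0)
  expect_equal(as.numeric(net$tables$fall_next_hour["yes"]), 0.30)

  # large alpha pulls every row towards uniform
  net2 <- fit_parameters(spec1, d, alpha = 1e9)
  expect_equal(as.numeric(net2$tables$fall_next_hour), c(0.5, 0.5),
               tolerance = 1e-6)

  # three-node chain with hand-tallied conditional frequencies
  spec3 <- toy_spec3()
  d3 <- data.frame(
    t = c("no", "no", "no", "no", "yes", "yes", "yes", "no"),
    a = c("lo", "lo", "hi", "hi", "hi", "hi", "lo", "lo"),
    b = c("lo", "hi", "hi", "hi", "lo", "hi", "hi", "lo"))
  net3 <- fit_parameters(spec3, d3, alpha = 0)
  expect_equal(as.numeric(net3$tables$t), c(5, 3) / 8)
  # P(a = hi | t = no) = 2/5 ; P(a = hi | t = yes) = 2/3
  expect_equal(net3$tables$a["hi", "no"], 2 / 5)
  expect_equal(net3$tables$a["hi", "yes"], 2 / 3)
  # P(b = hi | a = lo) = 2/4 ; P(b = hi | a = hi) = 3/4
  expect_equal(net3$tables$b["hi", "lo"], 2 / 4)
  expect_equal(net3$tables$b["hi", "hi"], 3 / 4)
  # every conditional distribution is normalised
  expect_equal(sum(net3$tables$t), 1, tolerance = 1e-9)
  expect_equal(unname(colSums(net3$tables$a)), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(colSums(net3$tables$b)), c(1, 1), tolerance = 1e-9)

  expect_error(fit_parameters(spec3, d3[, 1:2], 1), "lacks columns")
  d_bad <- d3; d_bad$a[1] <- "weird"
  expect_error(fit_parameters(spec3, d_bad, 1), "outside its declared states")
})

test_that("posteriors agree with brute-force enumeration on toys", {
  # 4-node network, handcrafted evidence
  net <- random_network(404, max_nodes = 4)
  expect_equal(posterior_fall_risk(net)$probability, enum_posterior(net),
               tolerance = 1e-12)
  ev <- random_evidence(net, 1)
  if (length(ev))
    expect_equal(posterior_fall_risk(net, ev)$probability,
                 enum_posterior(net, ev), tolerance = 1e-12)
})

test_that("posterior equals prior with no or uninformative evidence", {
  spec3 <- toy_spec3()
  d3 <- data.frame(t = rep(c("no", "yes"), c(60, 40)),
                   a = rep(c("lo", "hi"), 50),
                   b = rep(c("lo", "hi", "hi", "lo"), 25))
  net <- fit_parameters(spec3, d3, alpha = 0)
  p0 <- posterior_fall_risk(net)
  expect_equal(p0$probability, 0.4, tolerance = 1e-12)
  # a and b are independent of t by construction here
  expect_equal(posterior_fall_risk(net, list(a = "hi", b = "lo"))$probability,
               0.4, tolerance = 1e-12)
})

test_that("impossible evidence raises an explicit error", {
  spec <- build_network(list(
    nodes = list(
      list(name = "t", states = list("no", "yes"), construct = "target"),
      list(name = "a", states = list("l", "h"), construct = "c1")),
    edges = list(list("t", "a"))))
  d <- data.frame(t = rep(c("no", "yes"), c(5, 5)), a = rep("l", 10))
  net <- fit_parameters(spec, d, alpha = 0)   # P(a = h) = 0 everywhere
  expect_error(posterior_fall_risk(net, list(a = "h")), "inconsistent")
  expect_error(predict_risk(net, data.frame(a = "h")), "probability zero")
})

test_that("inference matches enumeration on random networks", {
  for (s in 1:30) {
    net <- random_network(s)
    ev <- random_evidence(net, s + 1000)
    oracle <- enum_posterior(net, ev)
    if (is.na(oracle)) next
    expect_equal(posterior_fall_risk(net, ev)$probability, oracle,
                 tolerance = 1e-12)
  }
})

test_that("batch prediction equals per-row posteriors on the packaged tree", {
  prof <- site_profiles()
  co <- generate_site_cohort(prof[prof$site_id == "A", ], 60, seed = 8)
  spec <- fp_network_spec()
  X <- derive_construct_summaries(build_feature_matrix(co, spec), spec)
  net <- fit_parameters(spec, X, alpha = 1)
  sub <- X[sample(nrow(X), 25), ]
  batch <- predict_risk(net, sub)
  ev_cols <- setdiff(intersect(names(spec$nodes), names(sub)), "fall_next_hour")
  for (i in seq_len(nrow(sub))) {
    ev <- as.list(sub[i, ev_cols])
    expect_equal(batch[i], posterior_fall_risk(net, ev)$probability,
                 tolerance = 1e-10)
  }
})

test_that("risk factors are the findings with likelihood ratio above 1", {
  net <- random_network(77, max_nodes = 6)
  ev <- random_evidence(net, 7)
  if (!length(ev)) ev <- stats::setNames(
    list(net$spec$nodes[[2]]$states[1]), names(net$spec$nodes)[2])
  pred <- posterior_fall_risk(net, ev)
  prior_odds <- pred$prior / (1 - pred$prior)
  for (v in names(ev)) {
    p1 <- enum_posterior(net, ev[v])
    lr <- (p1 / (1 - p1)) / prior_odds
    in_list <- v %in% pred$active_risk_factors$node
    expect_equal(in_list, is.finite(lr) && lr > 1)
  }
})

test_that("ancestral samples reproduce the generating distribution", {
  net <- random_network(55, max_nodes = 5)
  d <- sample_network(net, 40000, seed = 3)
  refit <- fit_parameters(net$spec, d, alpha = 0)
  # prior of the target matches within sampling error
  p_true <- enum_posterior(net)
  p_fit <- enum_posterior(refit)
  expect_lt(abs(p_true - p_fit), 0.015)
})

test_that("variance reduction matches the enumerated joint", {
  net <- random_network(31, max_nodes = 6)
  for (cstr in network_constructs(net$spec)) {
    expect_equal(variance_reduction(net, cstr),
                 max(0, enum_variance_reduction(net, cstr)),
                 tolerance = 1e-10)
  }
})

test_that("variance reduction hits its analytic extremes", {
  # construct independent of the target: zero reduction
  spec <- build_network(list(
    nodes = list(
      list(name = "t", states = list("no", "yes"), construct = "target"),
      list(name = "a", states = list("l", "h"), construct = "c1")),
    edges = list()))
  d <- data.frame(t = rep(c("no", "yes"), c(60, 40)),
                  a = rep(c("l", "h"), 50))
  net <- fit_parameters(spec, d, alpha = 0)
  expect_equal(variance_reduction(net, "c1"), 0, tolerance = 1e-12)

  # construct that determines the target: removes all p(1-p)
  spec2 <- build_network(list(
    nodes = list(
      list(name = "t", states = list("no", "yes"), construct = "target"),
      list(name = "a", states = list("l", "h"), construct = "c1")),
    edges = list(list("t", "a"))))
  d2 <- data.frame(t = rep(c("no", "yes"), c(60, 40)),
                   a = rep(c("l", "h"), c(60, 40)))
  net2 <- fit_parameters(spec2, d2, alpha = 0)
  expect_equal(variance_reduction(net2, "c1"), 0.4 * 0.6, tolerance = 1e-12)

  expect_error(variance_reduction(net2, "nope"), "no feature nodes")
  expect_error(variance_reduction(net2, "c1", cap = 1), "cap")
})

test_that("variance-reduction shares sum to one", {
  net <- random_network(91, max_nodes = 7)
  vp <- vr_profile(net)
  if (any(vp$vr > 0)) expect_equal(sum(vp$share), 1, tolerance = 1e-9)
})

test_that("construct ablation removes nodes and preserves validity", {
  spec <- fp_network_spec()
  ab <- ablate_construct(spec, "heuristic_tool")
  expect_false("heuristic_band" %in% names(ab$nodes))
  expect_false(any(ab$edges == "heuristic_band"))
  expect_s3_class(ab, "fp_network_spec")
  # ablating an absent construct is the identity
  expect_equal(ablate_construct(spec, "not_there"), spec)
  expect_error(ablate_construct(spec, "target"), "cannot ablate")
  # removing every non-target construct leaves the prior-only model
  solo <- keep_constructs(spec, character(0))
  expect_equal(names(solo$nodes), "fall_next_hour")
})
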