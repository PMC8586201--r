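test_that("an empty scenario reproduces the base case exactly", {
  tw <- tw_fixture()
  base <- run_cea(tw)
  res <- run_scenario(tw, scenario_spec("noop"))
  expect_identical(res$d_cost, base$d_cost)
  expect_identical(res$d_qaly, base$d_qaly)
  expect_identical(res$icer_per_qaly, base$icer_per_qaly)
})

test_that("scenario application is pure and validates override keys", {
  tw <- tw_fixture()
  snapshot <- unserialize(serialize(tw, NULL))
  s2 <- apply_scenario(tw, taiwan_scenarios()$equal_cv_mortality)
  expect_equal(s2$intervention$p_cvd, tw$comparator$p_cvd)
  expect_identical(tw, snapshot)  # base setting untouched
  expect_error(run_scenario(tw, scenario_spec("bad", list(foo = 1))),
               "unknown override key")
  expect_error(run_scenario(tw, scenario_spec("bad", list("econ.nope" = 1))),
               "unknown override field 'nope'")
  expect_error(apply_scenario(tw, scenario_spec("bad",
                                                list("intervention.p_cvd" = 2))),
               "p_cvd")
})

test_that("equal-risk directives copy the comparator's value", {
  tw <- tw_fixture()
  for (f in c("p_cvd", "p_ncd", "p_hhf")) {
    ov <- list("comparator"); names(ov) <- paste0("intervention.", f)
    s2 <- apply_scenario(tw, scenario_spec(f, ov))
    expect_identical(s2$intervention[[f]], tw$comparator[[f]])
  }
})

test_that("a zero perturbation range produces an all-zero-width tornado", {
  to <- one_way_sa(tw_fixture(), relative_range = 0)
  expect_true(all(to$width == 0))
})

test_that("the tornado ranks cardiovascular death risk as most influential", {
  to <- one_way_sa(tw_fixture(), relative_range = 0.10)
  expect_true(all(diff(to$width) <= 0))          # sorted by descending width
  expect_match(to$parameter[1], "p_cvd")
  # a parameter with no effect on increments: the comparator's zero drug cost
  expect_equal(to$width[to$parameter == "comparator.drug_cost"], 0)
})

test_that("the ICER is strictly increasing and affine in the drug price", {
  tw <- tw_fixture()
  prices <- c(0, 10, 35, 70, 140)
  icers <- vapply(prices, function(p) {
    run_scenario(tw, scenario_spec("p", list("intervention.drug_cost" = p)))$icer_per_qaly
  }, numeric(1))
  expect_true(all(diff(icers) > 0))
  slopes <- diff(icers) / diff(prices)
  expect_lt(max(slopes) - min(slopes), 1e-6 * mean(slopes))  # affine
})

test_that("the threshold price solver round-trips through the forward model", {
  tw <- tw_fixture()
  for (wtp in c(15000, 25000)) {
    price <- threshold_drug_price(tw, wtp)
    res <- run_scenario(tw, scenario_spec("thr",
                                          list("intervention.drug_cost" = price)))
    expect_lt(abs(res$icer_per_qaly - wtp), 10)  # 0.01 US$ price tol x slope
  }
  # fixed point: solving at the base ICER returns the base price
  base_icer <- run_cea(tw)$icer_per_qaly
  expect_lt(abs(threshold_drug_price(tw, base_icer) - 35), 0.05)
  expect_error(threshold_drug_price(tw, 1), "no threshold price")
})

test_that("adverse events shift costs and QALYs in the expected direction", {
  tw <- tw_fixture()
  base <- run_cea(tw)
  expect_identical(run_with_adverse_events(tw, list())$icer_per_qaly,
                   base$icer_per_qaly)
  # intervention-only burden: costlier and less effective -> higher ICER
  ae <- adverse_event("infection", p_intervention = 0.01, p_comparator = 0,
                      cost = 500, disutility = -0.1)
  worse <- run_with_adverse_events(tw, list(ae))
  expect_gt(worse$icer_per_qaly, base$icer_per_qaly)
  expect_gt(worse$d_cost, base$d_cost)
  expect_lt(worse$d_qaly, base$d_qaly)
})

test_that("symmetric adverse events cancel when the arms share one survival curve", {
  tw <- tw_fixture()
  spec <- scenario_spec("same risks", list("intervention.p_hhf" = "comparator",
                                           "intervention.p_cvd" = "comparator",
                                           "intervention.p_ncd" = "comparator"))
  same <- apply_scenario(tw, spec)
  base <- run_cea(same)
  ae <- adverse_event("both arms", p_intervention = 0.02, p_comparator = 0.02,
                      cost = 800, disutility = -0.05)
  res <- run_with_adverse_events(same, list(ae))
  expect_lt(abs(res$d_cost - base$d_cost), 1e-9)
  expect_lt(abs(res$d_qaly - base$d_qaly), 1e-12)
})
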