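test_that("discount factors follow the chosen compounding convention", {
  expect_equal(discount_factor(1, 0.03), 1)
  expect_equal(discount_factor(13, 0.03), 1 / 1.03)
  expect_equal(discount_factor(7, 0.03), 1.03^(-0.5))
  expect_equal(discount_factor(1:50, 0), rep(1, 50))
  # annual stepping holds the factor constant within each model year
  expect_equal(discount_factor(12, 0.03, "annual"), 1)
  expect_equal(discount_factor(13, 0.03, "annual"), 1 / 1.03)
})

test_that("vectorised accumulation matches the per-cycle brute-force oracle", {
  set.seed(51)
  for (i in 1:25) {
    arm <- random_valid_arm()
    econ <- toy_econ(r = runif(1, 0, 0.1))
    s <- model_settings(horizon_cycles = sample(12:120, 1),
                        accrual_months = sample(c(1, 2), 1),
                        first_cycle_event_free = sample(c(TRUE, FALSE), 1),
                        half_cycle_correction = sample(c(TRUE, FALSE), 1),
                        discount_method = sample(c("monthly", "annual"), 1),
                        age_step = sample(c("continuous", "annual"), 1))
    tr <- run_cohort(arm, s)
    got <- accumulate(tr, arm, econ, s)
    want <- accumulate_oracle(tr, arm, econ, s)
    expect_lt(abs(got$cost - want$cost), 1e-9 * max(1, want$cost))
    expect_lt(abs(got$qaly - want$qaly), 1e-9)
    expect_lt(abs(got$ly - want$ly), 1e-9)
  }
})

test_that("an event-free year at calendar accrual gives one life-year", {
  arm <- arm_parameters("null", 0, 0, 0, 0)
  s <- model_settings(horizon_cycles = 12, accrual_months = 1)
  econ <- economic_inputs(0.770, -0.0016, -0.321, 0, 0, 0, 0,
                          discount_rate_annual = 0)
  tot <- accumulate(run_cohort(arm, s), arm, econ, s)
  expect_equal(tot$ly, 1)
  # hand-computed: mean utility over the year with the continuous age decrement
  expect_equal(tot$qaly, sum(0.770 - 0.0016 * (0:11) / 12) / 12)
})

test_that("costs are linear in unit costs and QALYs are unaffected by them", {
  tw <- tw_fixture()
  arm <- tw$intervention
  tr <- run_cohort(arm, tw$settings)
  base <- accumulate(tr, arm, tw$econ, tw$settings)
  arm2 <- arm
  arm2$drug_cost <- 2 * arm$drug_cost
  econ2 <- tw$econ
  for (f in c("cost_stable", "cost_hhf", "cost_pre_cvd", "cost_pre_ncd"))
    econ2[[f]] <- 2 * econ2[[f]]
  doubled <- accumulate(tr, arm2, econ2, tw$settings)
  expect_equal(doubled$cost, 2 * base$cost)
  expect_equal(doubled$qaly, base$qaly)
  expect_equal(doubled$ly, base$ly)
})

test_that("totals decrease strictly as the discount rate rises", {
  tw <- tw_fixture()
  arm <- tw$intervention
  tr <- run_cohort(arm, tw$settings)
  tots <- lapply(c(0, 0.03, 0.10), function(r) {
    econ <- tw$econ; econ$discount_rate_annual <- r
    accumulate(tr, arm, econ, tw$settings)
  })
  expect_gt(tots[[1]]$cost, tots[[2]]$cost)
  expect_gt(tots[[2]]$cost, tots[[3]]$cost)
  expect_gt(tots[[1]]$qaly, tots[[2]]$qaly)
  expect_gt(tots[[2]]$qaly, tots[[3]]$qaly)
})

test_that("comparison labels the dominance cases and the ICER sign cases", {
  mk <- function(cost, qaly, ly = qaly) {
    structure(list(name = "x", cost = cost, qaly = qaly, ly = ly),
              class = "arm_totals")
  }
  r <- compare(mk(200, 3), mk(100, 2))
  expect_equal(r$icer_per_qaly, 100)
  expect_equal(r$label, "icer")
  expect_equal(compare(mk(99, 2.1), mk(100, 2))$label, "dominant")
  expect_equal(compare(mk(101, 1.9), mk(100, 2))$label, "dominated")
  expect_equal(compare(mk(100, 2), mk(100, 2))$label, "undefined")
  expect_true(is.na(compare(mk(100, 2), mk(100, 2))$icer_per_qaly))
})

test_that("net monetary benefit is zero exactly at the ICER", {
  tw <- tw_fixture()
  res <- run_cea(tw)
  expect_equal(net_monetary_benefit(res, res$icer_per_qaly), 0,
               tolerance = 1e-9)
  expect_gt(net_monetary_benefit(res, res$icer_per_qaly + 1), 0)
  expect_lt(net_monetary_benefit(res, res$icer_per_qaly - 1), 0)
  zero <- compare(structure(list(name = "a", cost = 1, qaly = 1, ly = 1),
                            class = "arm_totals"),
                  structure(list(name = "b", cost = 1, qaly = 1, ly = 1),
                            class = "arm_totals"))
  expect_equal(net_monetary_benefit(zero, 50000), 0)
})

test_that("the ICER is invariant to utility-free cost rescaling of both arms", {
  # scale every cost by k: increments scale by k, QALYs fixed -> ICER scales by k
  tw <- tw_fixture()
  base <- run_cea(tw)
  scaled <- fabricate_country(seed = 1, cost_scale = 3, jitter = 0)
  res <- run_cea(scaled)
  expect_equal(res$d_cost, 3 * base$d_cost, tolerance = 1e-12)
  expect_equal(res$d_qaly, base$d_qaly, tolerance = 1e-12)
  expect_equal(res$icer_per_qaly, 3 * base$icer_per_qaly, tolerance = 1e-12)
})

test_that("QALYs never exceed life-years and both respect the accrual bound", {
  set.seed(61)
  for (i in 1:20) {
    arm <- random_valid_arm()
    s <- model_settings(horizon_cycles = 60, accrual_months = sample(c(1, 2), 1))
    tot <- accumulate(run_cohort(arm, s), arm, toy_econ(), s)
    expect_gte(tot$qaly, 0)
    expect_lte(tot$qaly, tot$ly + 1e-12)
    expect_lte(tot$ly, s$accrual_months * 60 / 12 + 1e-12)
  }
})
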