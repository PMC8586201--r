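test_that("fixed distributions reproduce the base setting and base increments", {
  tw <- tw_fixture()
  fixed <- lapply(default_distributions(tw), function(d) {
    param_dist("fixed", d$mean)
  })
  s <- sample_parameters(tw, fixed, seed = 1)
  expect_equal(s$intervention, tw$intervention)
  expect_equal(s$comparator, tw$comparator)
  expect_equal(s$econ, tw$econ)

  base <- run_cea(tw)
  psa <- run_psa(tw, n = 1, seed = 1, distributions = fixed, n_patients = NULL)
  expect_equal(psa$draws$d_cost, base$d_cost)
  expect_equal(psa$draws$d_qaly, base$d_qaly)
})

test_that("the same seed reproduces a PSA bit-identically", {
  tw <- tw_fixture()
  a <- run_psa(tw, n = 50, seed = 42)
  b <- run_psa(tw, n = 50, seed = 42)
  expect_identical(a$draws, b$draws)
  expect_identical(a$ceac, b$ceac)
  c2 <- run_psa(tw, n = 50, seed = 43)
  expect_false(identical(a$draws, c2$draws))
  s1 <- sample_parameters(tw, seed = 7)
  s2 <- sample_parameters(tw, seed = 7)
  expect_identical(s1, s2)
})

test_that("sampled parameters respect their supports and stated moments", {
  tw <- tw_fixture()
  d <- param_dist("beta", 0.770, 0.016)
  set.seed(71)
  x <- hfcea:::draw_param(d, 1e5)
  expect_lt(abs(mean(x) - 0.770), 3 * 0.016 / sqrt(1e5))
  expect_true(all(x > 0 & x < 1))
  # disutility: beta on the magnitude, negated
  dd <- param_dist("beta", -0.321, 0.02)
  y <- hfcea:::draw_param(dd, 1e4)
  expect_true(all(y < 0 & y > -1))
  expect_lt(abs(mean(y) + 0.321), 4 * 0.02 / sqrt(1e4))
  # one full joint draw keeps every invariant (validated on construction)
  for (seed in 1:20) expect_s3_class(sample_parameters(tw, seed = seed),
                                     "country_setting")
  # infeasible beta moments fail at setup time
  expect_error(param_dist("beta", 0.5, 0.9), "infeasible")
})

test_that("relative-effect sampling preserves the arms' risk ratios", {
  tw <- tw_fixture()
  rr <- tw$intervention$p_cvd / tw$comparator$p_cvd
  for (seed in 1:10) {
    s <- sample_parameters(tw, seed = seed, arm_mode = "relative_effect")
    expect_equal(s$intervention$p_cvd / s$comparator$p_cvd, rr,
                 tolerance = 1e-12)
    expect_false(identical(s$comparator$p_cvd, tw$comparator$p_cvd))
  }
})

test_that("PSA increment means converge to the cohort base case", {
  tw <- tw_fixture()
  base <- run_cea(tw)
  # costs and utilities enter the accumulation linearly, so with the
  # transition probabilities held fixed the Monte-Carlo mean is an unbiased
  # estimator of the base increments: a clean 3-SE convergence check
  dists <- default_distributions(tw)
  for (k in grep("\\.p_", names(dists), value = TRUE))
    dists[[k]] <- param_dist("fixed", dists[[k]]$mean)
  psa <- run_psa(tw, n = 2000, seed = 5, distributions = dists,
                 n_patients = NULL)
  se_c <- sd(psa$draws$d_cost) / sqrt(2000)
  se_q <- sd(psa$draws$d_qaly) / sqrt(2000)
  expect_lt(abs(mean(psa$draws$d_cost) - base$d_cost), 3 * se_c)
  expect_lt(abs(mean(psa$draws$d_qaly) - base$d_qaly), 3 * se_q)

  # with sampled probabilities the model is nonlinear, so the PSA mean sits a
  # small Jensen gap away from the deterministic run; bound it at 3%
  full <- run_psa(tw, n = 2000, seed = 5, n_patients = NULL)
  expect_lt(abs(mean(full$draws$d_cost) - base$d_cost) / base$d_cost, 0.03)
  expect_lt(abs(mean(full$draws$d_qaly) - base$d_qaly) / base$d_qaly, 0.03)
})

test_that("patient-level sampling is unbiased for the cohort expectation", {
  tw <- tw_fixture()
  base <- run_cea(tw)
  set.seed(81)
  reps <- t(replicate(200, {
    r <- compare(
      hfcea:::sample_cohort_totals(tw$intervention, tw$econ, tw$settings, 2000),
      hfcea:::sample_cohort_totals(tw$comparator, tw$econ, tw$settings, 2000)
    )
    c(r$d_cost, r$d_qaly)
  }))
  expect_lt(abs(mean(reps[, 1]) - base$d_cost), 3 * sd(reps[, 1]) / sqrt(200))
  expect_lt(abs(mean(reps[, 2]) - base$d_qaly), 3 * sd(reps[, 2]) / sqrt(200))
})

test_that("the acceptability curve matches direct recounts and its limits", {
  tw <- tw_fixture()
  psa <- run_psa(tw, n = 300, seed = 9, wtp_grid = c(0, 25000, 75000, 1e9))
  d <- psa$draws
  expect_equal(psa$ceac$prob_ce[psa$ceac$wtp == 0], mean(d$d_cost < 0))
  expect_equal(psa$ceac$prob_ce[psa$ceac$wtp == 25000],
               mean(25000 * d$d_qaly - d$d_cost > 0))
  expect_equal(psa$ceac$prob_ce[psa$ceac$wtp == 75000],
               mean(75000 * d$d_qaly - d$d_cost > 0))
  expect_equal(psa$ceac$prob_ce[psa$ceac$wtp == 1e9], mean(d$d_qaly > 0),
               tolerance = 1e-12)
  # step-monotone when every draw gains QALYs
  if (all(d$d_qaly >= 0)) {
    cv <- ceac(psa, seq(0, 1e5, by = 5000))
    expect_true(all(diff(cv$prob_ce) >= 0))
  }
})
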