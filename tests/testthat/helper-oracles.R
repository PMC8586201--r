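# Shared fixtures and independent oracles used across test files.

tw_fixture <- function(...) taiwan_setting(...)

# a small arbitrary arm far from the Taiwan values, for generic checks
toy_arm <- function(name = "toy", p_hhf = 0.02, p_cvd = 0.01, p_ncd = 0.005,
                    drug_cost = 10) {
  arm_parameters(name, p_hhf, p_cvd, p_ncd, drug_cost)
}

toy_econ <- function(r = 0.03) {
  economic_inputs(u_stable = 0.8, u_age_decrement = -0.002,
                  u_hhf_decrement = -0.3, cost_stable = 100, cost_hhf = 1000,
                  cost_pre_cvd = 2000, cost_pre_ncd = 1500,
                  discount_rate_annual = r)
}

# Brute-force per-cycle accumulation, written directly from the accounting
# definitions with explicit loops and scalars; the implementation under test
# is vectorised, so this stays an independent route to the same totals.
accumulate_oracle <- function(trace, arm, econ, settings) {
  cost <- qaly <- ly <- 0
  n <- nrow(trace)
  for (t in seq_len(n)) {
    yrs <- if (settings$discount_method == "monthly") (t - 1) / 12
           else floor((t - 1) / 12)
    df <- (1 + econ$discount_rate_annual)^(-yrs)
    aoff <- if (settings$age_step == "continuous") (t - 1) / 12
            else floor((t - 1) / 12)
    u <- max(econ$u_stable + econ$u_age_decrement * aoff, 0)
    occ <- trace$alive[t]
    if (settings$half_cycle_correction) {
      nxt <- if (t < n) trace$alive[t + 1]
             else trace$alive[n] - trace$cvd[n] - trace$ncd[n]
      occ <- (trace$alive[t] + nxt) / 2
    }
    a <- settings$accrual_months * occ
    cost <- cost + df * (a * (arm$drug_cost + econ$cost_stable) +
                           trace$hhf[t] * econ$cost_hhf +
                           trace$cvd[t] * econ$cost_pre_cvd +
                           trace$ncd[t] * econ$cost_pre_ncd)
    qaly <- qaly + df * (a * u + trace$hhf[t] * econ$u_hhf_decrement) / 12
    ly <- ly + df * a / 12
  }
  list(cost = cost, qaly = qaly, ly = ly)
}

random_valid_arm <- function() {
  repeat {
    p <- stats::runif(3, 0, 0.15)
    if (p[2] + p[3] < 1) break
  }
  arm_parameters("rand", p[1], p[2], p[3], stats::runif(1, 0, 100))
}
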