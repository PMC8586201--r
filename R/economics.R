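#' Discount factor for a model cycle
#'
#' Cycle 1 is undiscounted. With `method = "monthly"` (default) the factor is
#' `(1 + annual_rate)^(-(cycle - 1)/12)`; with `"annual"` discounting steps
#' once per model year, `(1 + annual_rate)^(-floor((cycle - 1)/12))`.
#'
#' @param cycle Cycle index (1-based), may be a vector.
#' @param annual_rate Annual discount rate (fraction, >= 0).
#' @param method `"monthly"` or `"annual"`.
#' @return Discount multiplier(s) in (0, 1].
#' @examples
#' discount_factor(13, 0.03) # one elapsed year: 1/1.03
#' @export
discount_factor <- function(cycle, annual_rate, method = c("monthly", "annual")) {
  method <- match.arg(method)
  stopifnot(all(cycle >= 1), annual_rate >= 0)
  yrs <- if (method == "monthly") (cycle - 1) / 12 else floor((cycle - 1) / 12)
  (1 + annual_rate)^(-yrs)
}

#' Accumulate discounted costs, QALYs and life-years over a cohort trace
#'
#' Converts a [run_cohort()] trace into per-arm totals. Each cycle
#' contributes:
#' \itemize{
#'   \item cost: `A x occupancy x (drug_cost + cost_stable) + hhf x cost_hhf +
#'     cvd x cost_pre_cvd + ncd x cost_pre_ncd`,
#'   \item QALYs: `(A x occupancy x u(age) + hhf x u_hhf_decrement) / 12`,
#'   \item life-years: `A x occupancy / 12`,
#' }
#' all multiplied by the cycle's discount factor, where
#' `u(age) = u_stable + u_age_decrement x (age - start_age)` (clamped at 0
#' with a warning if the age decrement drives it negative), `occupancy` is the
#' alive fraction at cycle start (or the mid-cycle mean under the half-cycle
#' correction), and `A = settings$accrual_months` is the state-reward accrual
#' convention (see [model_settings()]). One-off event rewards (`hhf`, `cvd`,
#' `ncd` terms) accrue once per event. Dead states accrue nothing.
#'
#' @param trace A `cohort_trace` produced under the same `settings`.
#' @param arm The [arm_parameters()] the trace was run with.
#' @param econ An [economic_inputs()] object.
#' @param settings The [model_settings()] used for the trace.
#' @param adverse_events Optional list of [adverse_event()] specifications;
#'   each adds an expected per-cycle cost `occupancy x p x cost` and
#'   disutility `occupancy x p x decrement / 12` for the probability of the
#'   named arm.
#' @return An object of class `arm_totals`: list with `cost`, `qaly`, `ly`
#'   (discounted totals) and the arm `name`.
#' @export
accumulate <- function(trace, arm, econ, settings = model_settings(),
                       adverse_events = NULL) {
  stopifnot(inherits(trace, "cohort_trace"))
  n <- nrow(trace)
  df <- discount_factor(trace$cycle, econ$discount_rate_annual,
                        settings$discount_method)
  age_off <- if (settings$age_step == "continuous") (trace$cycle - 1) / 12
             else floor((trace$cycle - 1) / 12)
  u <- econ$u_stable + econ$u_age_decrement * age_off
  if (any(u < 0)) {
    warning("age decrement drives utility below 0 at cycle ",
            trace$cycle[which(u < 0)[1]], "; clamping to 0", call. = FALSE)
    u <- pmax(u, 0)
  }

  occ <- trace$alive
  if (settings$half_cycle_correction) {
    alive_next <- c(trace$alive[-1], trace$alive[n] - trace$cvd[n] - trace$ncd[n])
    occ <- (trace$alive + alive_next) / 2
  }
  state <- settings$accrual_months * occ

  cost_cycle <- state * (arm$drug_cost + econ$cost_stable) +
    trace$hhf * econ$cost_hhf +
    trace$cvd * econ$cost_pre_cvd +
    trace$ncd * econ$cost_pre_ncd
  qaly_cycle <- (state * u + trace$hhf * econ$u_hhf_decrement) / 12
  ly_cycle <- state / 12

  if (!is.null(adverse_events)) {
    for (ae in adverse_events) {
      p <- ae$p   # per-cycle probability already resolved for this arm
      stopifnot(is.numeric(p), p >= 0, p < 1, ae$cost >= 0, ae$disutility <= 0)
      cost_cycle <- cost_cycle + occ * p * ae$cost
      qaly_cycle <- qaly_cycle + occ * p * ae$disutility / 12
    }
  }

  structure(
    list(name = arm$name,
         cost = sum(df * cost_cycle),
         qaly = sum(df * qaly_cycle),
         ly = sum(df * ly_cycle)),
    class = "arm_totals"
  )
}

#' @export
print.arm_totals <- function(x, ...) {
  cat(sprintf("<arm_totals> %s: cost %.0f US$, %.3f QALYs, %.3f LYs (discounted)\n",
              x$name, x$cost, x$qaly, x$ly))
  invisible(x)
}

#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes incremental cost, QALYs and life-years of the intervention over
#' the comparator, the incremental cost-effectiveness ratios (US$/QALY and
#' US$/LY), and a dominance label: `"icer"` when more costly and more
#' effective, `"dominant"` (cheaper and more effective), `"dominated"`
#' (costlier and less effective), `"cost_saving_less_effective"` (cheaper,
#' less effective: the ratio is reported but reads as savings per QALY
#' forgone), or `"undefined"` when the QALY increment is below `tol`.
#'
#' @param intervention,comparator `arm_totals` from [accumulate()].
#' @param tol Absolute QALY increment below which the ICER is undefined.
#' @return An object of class `econ_result` with per-arm totals, increments,
#'   `icer_per_qaly`, `icer_per_ly` and `label`.
#' @export
compare <- function(intervention, comparator, tol = 1e-9) {
  stopifnot(inherits(intervention, "arm_totals"),
            inherits(comparator, "arm_totals"))
  d_cost <- intervention$cost - comparator$cost
  d_qaly <- intervention$qaly - comparator$qaly
  d_ly <- intervention$ly - comparator$ly

  label <- if (abs(d_qaly) < tol) "undefined"
    else if (d_cost <= 0 && d_qaly > 0) "dominant"
    else if (d_cost > 0 && d_qaly < 0) "dominated"
    else if (d_cost <= 0 && d_qaly < 0) "cost_saving_less_effective"
    else "icer"
  icer_q <- if (abs(d_qaly) < tol) NA_real_ else d_cost / d_qaly
  icer_l <- if (abs(d_ly) < tol) NA_real_ else d_cost / d_ly

  structure(
    list(intervention = intervention, comparator = comparator,
         d_cost = d_cost, d_qaly = d_qaly, d_ly = d_ly,
         icer_per_qaly = icer_q, icer_per_ly = icer_l, label = label),
    class = "econ_result"
  )
}

#' @export
print.econ_result <- function(x, ...) {
  cat("<econ_result>\n")
  cat(sprintf("  %-20s cost %10.0f  QALY %7.3f  LY %7.3f\n",
              x$intervention$name, x$intervention$cost, x$intervention$qaly,
              x$intervention$ly))
  cat(sprintf("  %-20s cost %10.0f  QALY %7.3f  LY %7.3f\n",
              x$comparator$name, x$comparator$cost, x$comparator$qaly,
              x$comparator$ly))
  cat(sprintf("  incremental: %+.0f US$, %+.4f QALY, %+.4f LY\n",
              x$d_cost, x$d_qaly, x$d_ly))
  if (x$label == "icer")
    cat(sprintf("  ICER: %.0f US$/QALY, %.0f US$/LY\n",
                x$icer_per_qaly, x$icer_per_ly))
  else
    cat(sprintf("  %s (ICER per QALY: %s)\n", x$label,
                ifelse(is.na(x$icer_per_qaly), "undefined",
                       sprintf("%.0f", x$icer_per_qaly))))
  invisible(x)
}

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' `NMB = dQALY x wtp - dCost`; positive iff the intervention is
#' cost-effective at that threshold.
#'
#' @param result An `econ_result` from [compare()] or [run_cea()].
#' @param wtp Willingness to pay, US$/QALY (>= 0).
#' @return Net monetary benefit in US$.
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(inherits(result, "econ_result"), wtp >= 0)
  result$d_qaly * wtp - result$d_cost
}

#' Run the full two-arm cost-effectiveness analysis for a setting
#'
#' Convenience wrapper: runs [run_cohort()] and [accumulate()] for both arms
#' of a [country_setting()] and returns the [compare()] result.
#'
#' @param setting A [country_setting()].
#' @param adverse_events Optional list of [adverse_event()] specs applied to
#'   both arms (each with its own per-arm probabilities).
#' @return An `econ_result`.
#' @examples
#' run_cea(taiwan_setting())
#' @export
run_cea <- function(setting, adverse_events = NULL) {
  stopifnot(inherits(setting, "country_setting"))
  s <- setting$settings
  tot <- lapply(c("intervention", "comparator"), function(side) {
    arm <- setting[[side]]
    tr <- run_cohort(arm, s)
    aes <- if (is.null(adverse_events)) NULL else lapply(adverse_events, function(ae) {
      stopifnot(inherits(ae, "adverse_event"))
      list(p = if (side == "comparator") ae$p_comparator else ae$p_intervention,
           cost = ae$cost, disutility = ae$disutility)
    })
    accumulate(tr, arm, setting$econ, s, adverse_events = aes)
  })
  compare(tot[[1]], tot[[2]])
}
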