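#' Run the monthly-cycle cohort simulation for one arm
#'
#' Simulates a closed cohort of stable heart-failure patients over
#' `settings$horizon_cycles` one-month cycles. At each cycle the fraction
#' alive at cycle start may be hospitalized for heart failure (a transient
#' within-cycle event: survivors return to stable HF), die of cardiovascular
#' cause, or die of non-cardiovascular cause; the three per-cycle event
#' fractions are `alive x p_event` (events treated as independent within a
#' cycle). Deaths are removed before the next cycle. Transition probabilities
#' are constant over time. When `settings$first_cycle_event_free` is set
#' (default) no events occur in cycle 1.
#'
#' @param arm An [arm_parameters()] object.
#' @param settings A [model_settings()] object.
#' @return A `cohort_trace`: a data frame with one row per cycle and columns
#'   `cycle`, `age` (years at cycle start), `alive` (fraction at cycle start),
#'   `hhf`, `cvd`, `ncd` (per-cycle event fractions), `cum_dead_cv`,
#'   `cum_dead_ncv` (cumulative death fractions by cause at cycle end).
#' @examples
#' tw <- taiwan_setting()
#' tr <- run_cohort(tw$intervention, tw$settings)
#' 1 - tr$alive[nrow(tr)] + tr$cvd[nrow(tr)] + tr$ncd[nrow(tr)] # mortality
#' @export
run_cohort <- function(arm, settings = model_settings()) {
  validate_arm_parameters(arm)
  n <- settings$horizon_cycles
  p_dead <- arm$p_cvd + arm$p_ncd

  # survival at cycle start: events start at cycle 2 when the first cycle is
  # event-free, at cycle 1 otherwise
  k_free <- if (settings$first_cycle_event_free) 1L else 0L
  cycle <- seq_len(n)
  n_exposed <- pmax(cycle - 1L - k_free, 0L)   # death-risk cycles before this one
  alive <- (1 - p_dead)^n_exposed

  at_risk <- as.numeric(cycle > k_free)
  hhf <- alive * arm$p_hhf * at_risk
  cvd <- alive * arm$p_cvd * at_risk
  ncd <- alive * arm$p_ncd * at_risk

  out <- data.frame(
    cycle = cycle,
    age = settings$start_age + (cycle - 1) / 12,
    alive = alive,
    hhf = hhf,
    cvd = cvd,
    ncd = ncd,
    cum_dead_cv = cumsum(cvd),
    cum_dead_ncv = cumsum(ncd)
  )
  class(out) <- c("cohort_trace", "data.frame")
  attr(out, "arm") <- arm$name
  out
}

#' Expected event counts for a cohort of given size
#'
#' Sums per-cycle event fractions over the trace and scales to a cohort size,
#' giving the expected numbers of heart-failure hospitalizations and deaths by
#' cause over the model horizon.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param per Cohort size to scale to (default 1000 patients).
#' @return A named numeric vector with elements `hhf`, `cv_death`,
#'   `non_cv_death`.
#' @examples
#' tw <- taiwan_setting()
#' expected_events(run_cohort(tw$comparator, tw$settings)) # ~1,099 HHF/1,000
#' @export
expected_events <- function(trace, per = 1000) {
  stopifnot(inherits(trace, "cohort_trace"))
  c(hhf = sum(trace$hhf) * per,
    cv_death = sum(trace$cvd) * per,
    non_cv_death = sum(trace$ncd) * per)
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<cohort_trace> arm '%s', %d monthly cycles\n",
              attr(x, "arm") %||% "?", n))
  surv <- x$alive[n] - x$cvd[n] - x$ncd[n]
  cat(sprintf("  surviving fraction at horizon: %.4f (mortality %.1f%%)\n",
              surv, 100 * (1 - surv)))
  ev <- expected_events(x, per = 1000)
  cat(sprintf("  per 1,000 patients: %.0f HHF, %.0f CV deaths, %.0f non-CV deaths\n",
              ev["hhf"], ev["cv_death"], ev["non_cv_death"]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
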