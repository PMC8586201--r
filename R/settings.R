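#' Model run settings
#'
#' Structural settings of the cohort simulation and the accounting conventions
#' used when accumulating costs and effects. The defaults are the conventions
#' under which the bundled Taiwan inputs reproduce their source results; see
#' the methods vignette for the evidence behind each choice.
#'
#' @param start_age Cohort age at model start, years.
#' @param horizon_cycles Number of monthly cycles to simulate (180 = 15 years).
#' @param cycle_length_months Cycle length; fixed at 1 month (the acute stage
#'   of a heart-failure hospitalization lasts about one month).
#' @param first_cycle_event_free If `TRUE` (default) no clinical events occur
#'   in the first cycle: the cohort enters in stable heart failure.
#' @param half_cycle_correction If `TRUE`, state rewards are accrued on the
#'   mid-cycle occupancy (mean of cycle-start and next cycle-start); default
#'   `FALSE` (cycle-start occupancy).
#' @param accrual_months Months of state-occupancy reward (chronic cost, drug
#'   cost, utility, life-time) credited per one-month cycle. The default, 2,
#'   is the accounting convention of the reference analysis from which the
#'   bundled Taiwan inputs are taken (equivalent to transitions on a
#'   half-month grid with monthly-sized rewards); set to 1 for strict
#'   calendar-time accounting. One-off event rewards (hospitalization cost and
#'   disutility, pre-death costs) always accrue once per event.
#' @param discount_method `"monthly"` (default): continuous monthly
#'   compounding, discount factor `(1+r)^(-(cycle-1)/12)`; `"annual"`: stepwise
#'   annual discounting, `(1+r)^(-floor((cycle-1)/12))`.
#' @param age_step `"continuous"` (default): cohort age advances by 1/12 year
#'   per cycle for the utility age decrement; `"annual"`: age advances in
#'   whole-year steps.
#' @return An object of class `model_settings`.
#' @export
model_settings <- function(start_age = 67,
                           horizon_cycles = 180,
                           cycle_length_months = 1,
                           first_cycle_event_free = TRUE,
                           half_cycle_correction = FALSE,
                           accrual_months = 2,
                           discount_method = c("monthly", "annual"),
                           age_step = c("continuous", "annual")) {
  discount_method <- match.arg(discount_method)
  age_step <- match.arg(age_step)
  if (!is.numeric(start_age) || start_age <= 0)
    stop("start_age must be > 0", call. = FALSE)
  if (!is.numeric(horizon_cycles) || horizon_cycles < 1 ||
      horizon_cycles != round(horizon_cycles))
    stop("horizon_cycles must be an integer >= 1", call. = FALSE)
  if (cycle_length_months != 1)
    stop("cycle_length_months is fixed at 1 month in this model", call. = FALSE)
  if (!is.numeric(accrual_months) || accrual_months <= 0)
    stop("accrual_months must be > 0", call. = FALSE)
  structure(
    list(start_age = start_age,
         horizon_cycles = as.integer(horizon_cycles),
         cycle_length_months = 1,
         first_cycle_event_free = isTRUE(first_cycle_event_free),
         half_cycle_correction = isTRUE(half_cycle_correction),
         accrual_months = accrual_months,
         discount_method = discount_method,
         age_step = age_step),
    class = "model_settings"
  )
}

#' @export
print.model_settings <- function(x, ...) {
  cat("<model_settings>\n")
  cat(sprintf("  start age %g y, %d monthly cycles (%.1f y horizon)\n",
              x$start_age, x$horizon_cycles, x$horizon_cycles / 12))
  cat(sprintf("  first cycle event-free: %s; half-cycle correction: %s\n",
              x$first_cycle_event_free, x$half_cycle_correction))
  cat(sprintf("  state-reward accrual: %g month(s)/cycle; discounting: %s; age step: %s\n",
              x$accrual_months, x$discount_method, x$age_step))
  invisible(x)
}

#' Country-level model setting
#'
#' A complete, validated model configuration for one country: the two
#' treatment arms (intervention and comparator), the economic inputs, run
#' settings, willingness-to-pay thresholds (1x and 3x GDP per capita), and
#' optionally the standard errors that parameterise probabilistic sensitivity
#' analysis distributions.
#'
#' @param label Country or setting name.
#' @param intervention,comparator [arm_parameters()] objects.
#' @param econ An [economic_inputs()] object.
#' @param settings A [model_settings()] object.
#' @param wtp_1x,wtp_3x Willingness-to-pay thresholds, US$/QALY, with
#'   `0 <= wtp_1x <= wtp_3x`.
#' @param se Optional named list of standard errors mirroring the parameter
#'   structure (`intervention`, `comparator`, `econ` sub-lists); consumed by
#'   [default_distributions()].
#' @return An object of class `country_setting`.
#' @seealso [taiwan_setting()] for the bundled Taiwan configuration,
#'   [load_setting()]/[save_setting()] for file round-trips.
#' @export
country_setting <- function(label, intervention, comparator, econ,
                            settings = model_settings(),
                            wtp_1x = 25000, wtp_3x = 75000, se = NULL) {
  if (!inherits(intervention, "arm_parameters") ||
      !inherits(comparator, "arm_parameters"))
    stop("intervention and comparator must be arm_parameters objects",
         call. = FALSE)
  if (!inherits(econ, "economic_inputs"))
    stop("econ must be an economic_inputs object", call. = FALSE)
  if (!inherits(settings, "model_settings"))
    stop("settings must be a model_settings object", call. = FALSE)
  if (wtp_1x < 0 || wtp_3x < wtp_1x)
    stop("need 0 <= wtp_1x <= wtp_3x", call. = FALSE)
  validate_arm_parameters(intervention)
  validate_arm_parameters(comparator)
  validate_economic_inputs(econ)
  structure(
    list(label = as.character(label), intervention = intervention,
         comparator = comparator, econ = econ, settings = settings,
         wtp_1x = wtp_1x, wtp_3x = wtp_3x, se = se),
    class = "country_setting"
  )
}

#' @export
print.country_setting <- function(x, ...) {
  cat(sprintf("<country_setting> %s (WTP %s / %s US$/QALY)\n", x$label,
              format(x$wtp_1x, big.mark = ","), format(x$wtp_3x, big.mark = ",")))
  print(x$intervention)
  print(x$comparator)
  cat(sprintf("  u_stable %.3f, chronic cost %.0f US$/mo, HHF cost %.0f US$, discount %.1f%%/y\n",
              x$econ$u_stable, x$econ$cost_stable, x$econ$cost_hhf,
              100 * x$econ$discount_rate_annual))
  invisible(x)
}
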