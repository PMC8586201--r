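#' Bundled Taiwan base-case setting
#'
#' The fully parameterised Taiwan configuration: monthly transition
#' probabilities derived from 16-month trial event proportions under constant
#' hazards, utilities from published EQ-5D/KCCQ sources, and 2020-US$ costs
#' estimated from national claims data. Standard errors accompany every
#' parameter for probabilistic sensitivity analysis (beta for probabilities
#' and utilities, gamma for costs; cost standard errors are half the mean).
#' The same values ship as a config file in
#' `system.file("extdata", "taiwan_base.yaml", package = "hfcea")`.
#'
#' @param settings A [model_settings()] object; defaults to the base-case run
#'   settings (start age 67, 180 monthly cycles, 3% annual discount carried in
#'   the economic inputs).
#' @return A [country_setting()] object labelled `"Taiwan"`.
#' @examples
#' tw <- taiwan_setting()
#' res <- run_cea(tw)
#' res$icer_per_qaly
#' @export
taiwan_setting <- function(settings = model_settings()) {
  country_setting(
    label = "Taiwan",
    intervention = arm_parameters(
      name = "empagliflozin",
      p_hhf = 0.008811915, p_cvd = 0.006589325, p_ncd = 0.002113141,
      drug_cost = 35
    ),
    comparator = arm_parameters(
      name = "standard therapy",
      p_hhf = 0.012566527, p_cvd = 0.007131185, p_ncd = 0.002177683,
      drug_cost = 0
    ),
    econ = economic_inputs(
      u_stable = 0.770, u_age_decrement = -0.0016, u_hhf_decrement = -0.321,
      cost_stable = 450, cost_hhf = 2887,
      cost_pre_cvd = 3430, cost_pre_ncd = 3390,
      discount_rate_annual = 0.03
    ),
    settings = settings,
    wtp_1x = 25000, wtp_3x = 75000,
    se = list(
      intervention = list(p_hhf = 0.002165244, p_cvd = 0.00187447,
                          p_ncd = 0.001063894, drug_cost = 17.5),
      comparator = list(p_hhf = 0.002578038, p_cvd = 0.001947398,
                        p_ncd = 0.001078827, drug_cost = 0),
      econ = list(u_stable = 0.016, u_age_decrement = 0.0001,
                  u_hhf_decrement = 0.02, cost_stable = 225,
                  cost_hhf = 1443.5, cost_pre_cvd = 1715, cost_pre_ncd = 1695)
    )
  )
}

#' Bundled scenario specifications for the Taiwan setting
#'
#' The standard scenario suite: equalised per-arm risks (intervention set to
#' the comparator's value), halved drug and hospitalization costs, alternative
#' horizons (16 months, 30 years) and discount rates (0%, 10%).
#'
#' @return A named list of [scenario_spec()] objects.
#' @seealso [run_scenario()]
#' @export
taiwan_scenarios <- function() {
  list(
    equal_cv_mortality = scenario_spec(
      "Risk of cardiovascular mortality of intervention equal to comparator",
      overrides = list("intervention.p_cvd" = "comparator")),
    equal_non_cv_death = scenario_spec(
      "Risk of non-cardiovascular death of intervention equal to comparator",
      overrides = list("intervention.p_ncd" = "comparator")),
    equal_hhf = scenario_spec(
      "Risk of HHF of intervention equal to comparator",
      overrides = list("intervention.p_hhf" = "comparator")),
    half_drug_cost = scenario_spec(
      "Half the monthly drug cost (US$17.5)",
      overrides = list("intervention.drug_cost" = 17.5)),
    half_hhf_cost = scenario_spec(
      "Half the cost of HHF treatment (US$1,443.5)",
      overrides = list("econ.cost_hhf" = 1443.5)),
    horizon_30y = scenario_spec(
      "Time horizon 30 years",
      overrides = list("settings.horizon_cycles" = 360)),
    horizon_16m = scenario_spec(
      "Time horizon 16 months",
      overrides = list("settings.horizon_cycles" = 16)),
    discount_0 = scenario_spec(
      "Discount rate 0%",
      overrides = list("econ.discount_rate_annual" = 0)),
    discount_10 = scenario_spec(
      "Discount rate 10%",
      overrides = list("econ.discount_rate_annual" = 0.10))
  )
}
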