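#' Scenario specification
#'
#' A named set of parameter overrides applied on top of a base
#' [country_setting()]. Override keys are dotted paths into the setting:
#' `"intervention.p_cvd"`, `"comparator.drug_cost"`, `"econ.cost_hhf"`,
#' `"econ.discount_rate_annual"`, `"settings.horizon_cycles"`, and so on.
#' An arm-parameter override may be the string `"comparator"` or
#' `"intervention"` instead of a number, meaning "set this arm's value equal
#' to the other arm's" (used for the equal-risk scenarios).
#'
#' @param label Human-readable scenario name.
#' @param overrides Named list of overrides (may be empty).
#' @param adverse_events Optional list of [adverse_event()] specs.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(label, overrides = list(), adverse_events = NULL) {
  stopifnot(is.list(overrides))
  if (length(overrides) && is.null(names(overrides)))
    stop("overrides must be named", call. = FALSE)
  structure(list(label = label, overrides = overrides,
                 adverse_events = adverse_events),
            class = "scenario_spec")
}

#' Apply a scenario specification to a setting
#'
#' Pure function: returns a new validated [country_setting()]; the base
#' setting is never modified.
#'
#' @param setting A [country_setting()].
#' @param spec A [scenario_spec()].
#' @return The modified `country_setting`.
#' @export
apply_scenario <- function(setting, spec) {
  stopifnot(inherits(setting, "country_setting"), inherits(spec, "scenario_spec"))
  s <- setting
  for (key in names(spec$overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("unknown override key '", key, "': expected section.field", call. = FALSE)
    section <- parts[1]; field <- parts[2]
    if (!section %in% c("intervention", "comparator", "econ", "settings"))
      stop("unknown override section '", section, "' in key '", key, "'",
           call. = FALSE)
    if (!field %in% names(s[[section]]))
      stop("unknown override field '", field, "' in key '", key, "'",
           call. = FALSE)
    value <- spec$overrides[[key]]
    if (is.character(value) && section %in% c("intervention", "comparator")) {
      if (!value %in% c("intervention", "comparator"))
        stop("string override for '", key, "' must name an arm", call. = FALSE)
      value <- s[[value]][[field]]
    }
    if (!is.numeric(value) && !is.logical(value))
      stop("override '", key, "' must be numeric", call. = FALSE)
    if (section == "settings") {
      args <- unclass(s$settings)
      args[[field]] <- value
      s$settings <- do.call(model_settings, args)
    } else {
      s[[section]][[field]] <- value
    }
  }
  # re-validate everything the overrides may have touched
  country_setting(s$label, s$intervention, s$comparator, s$econ, s$settings,
                  s$wtp_1x, s$wtp_3x, s$se)
}

#' Run a scenario analysis
#'
#' Applies the scenario's overrides, reruns both arms, and returns the
#' incremental result. An empty scenario reproduces the base case exactly.
#'
#' @param setting Base [country_setting()].
#' @param spec A [scenario_spec()].
#' @return An `econ_result`.
#' @examples
#' run_scenario(taiwan_setting(), taiwan_scenarios()$half_drug_cost)
#' @export
run_scenario <- function(setting, spec) {
  run_cea(apply_scenario(setting, spec), adverse_events = spec$adverse_events)
}

#' Adverse-event specification for the extended model
#'
#' Models an adverse event (e.g. urinary/genital infection, hypoglycemia,
#' fracture) as an independent expected-value add-on: in each cycle the alive
#' fraction incurs probability x cost and probability x disutility/12, with
#' arm-specific monthly probabilities. No state change is induced.
#'
#' @param label Event name.
#' @param p_intervention,p_comparator Monthly event probability per arm, in
#'   `[0, 1)`.
#' @param cost Cost per event, US$ (>= 0).
#' @param disutility Utility decrement per event-month (<= 0).
#' @return An object of class `adverse_event`.
#' @export
adverse_event <- function(label, p_intervention, p_comparator, cost, disutility) {
  stopifnot(p_intervention >= 0, p_intervention < 1,
            p_comparator >= 0, p_comparator < 1,
            cost >= 0, disutility <= 0)
  structure(list(label = label, p_intervention = p_intervention,
                 p_comparator = p_comparator, cost = cost,
                 disutility = disutility),
            class = "adverse_event")
}

#' Rerun the model with adverse events included
#'
#' @param setting A [country_setting()].
#' @param events List of [adverse_event()] specs (empty list reproduces the
#'   base case exactly).
#' @return An `econ_result`.
#' @export
run_with_adverse_events <- function(setting, events) {
  if (length(events) == 0) return(run_cea(setting))
  run_cea(setting, adverse_events = events)
}

#' One-way (tornado) sensitivity analysis
#'
#' Recomputes the ICER with each input parameter in turn set to
#' `mean x (1 - relative_range)` and `mean x (1 + relative_range)`, holding
#' all others at base. Arm-specific parameters (transition probabilities, drug
#' cost) are perturbed per arm; shared economic parameters (utilities, costs,
#' discount rate) are perturbed once, affecting both arms. A perturbed value
#' that would leave its valid range is clamped to the boundary with a message.
#' Parameters whose base value is 0 produce zero-width entries.
#'
#' @param setting A [country_setting()].
#' @param relative_range Relative perturbation, in [0, 1); default 0.10 (0
#'   gives zero-width entries).
#' @return A data frame of class `tornado` with columns `parameter`,
#'   `value_low`, `value_high`, `icer_low`, `icer_high`, `width`, sorted by
#'   decreasing width.
#' @examples
#' head(one_way_sa(taiwan_setting()), 3)
#' @export
one_way_sa <- function(setting, relative_range = 0.10) {
  stopifnot(inherits(setting, "country_setting"),
            relative_range >= 0, relative_range < 1)
  base_icer <- run_cea(setting)$icer_per_qaly

  params <- c(
    paste0("intervention.", c("p_hhf", "p_cvd", "p_ncd", "drug_cost")),
    paste0("comparator.", c("p_hhf", "p_cvd", "p_ncd", "drug_cost")),
    paste0("econ.", c("u_stable", "u_age_decrement", "u_hhf_decrement",
                      "cost_stable", "cost_hhf", "cost_pre_cvd",
                      "cost_pre_ncd", "discount_rate_annual"))
  )

  one <- function(key, mult) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    base <- setting[[parts[1]]][[parts[2]]]
    val <- base * mult
    val <- clamp_param(parts[2], val)
    ov <- list(val); names(ov) <- key
    icer <- run_scenario(setting, scenario_spec(key, ov))$icer_per_qaly
    c(value = val, icer = icer)
  }

  rows <- lapply(params, function(key) {
    lo <- one(key, 1 - relative_range)
    hi <- one(key, 1 + relative_range)
    data.frame(parameter = key, value_low = lo["value"], value_high = hi["value"],
               icer_low = lo["icer"], icer_high = hi["icer"],
               width = abs(hi["icer"] - lo["icer"]), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  attr(out, "relative_range") <- relative_range
  class(out) <- c("tornado", "data.frame")
  out
}

clamp_param <- function(field, val) {
  if (startsWith(field, "p_") && val >= 1) {
    message("clamping ", field, " to 1 - 1e-12")
    val <- 1 - 1e-12
  }
  if (field == "u_stable" && val > 1) {
    message("clamping u_stable to 1")
    val <- 1
  }
  val
}

#' Threshold drug price for a willingness-to-pay limit
#'
#' Solves for the intervention's monthly drug cost at which the ICER equals
#' the willingness-to-pay threshold. The ICER is affine and strictly
#' increasing in the drug price (the incremental cost gains exactly the
#' discounted intervention person-time per US$ of price; the QALY increment is
#' unaffected), so a monotone root search over `[0, upper]` suffices.
#'
#' @param setting A [country_setting()]; must have a positive QALY increment
#'   at base.
#' @param wtp Willingness to pay, US$/QALY (> 0).
#' @param upper Upper search bound; defaults to 10x the base drug price (or
#'   350 if the base price is 0).
#' @param tol Price tolerance in US$ (default 0.01).
#' @return Monthly drug price in US$.
#' @examples
#' threshold_drug_price(taiwan_setting(), wtp = 25000)
#' @export
threshold_drug_price <- function(setting, wtp, upper = NULL, tol = 0.01) {
  stopifnot(inherits(setting, "country_setting"), wtp > 0)
  base <- run_cea(setting)
  if (base$d_qaly <= 0)
    stop("threshold price undefined: QALY increment is not positive at base",
         call. = FALSE)
  if (is.null(upper))
    upper <- if (setting$intervention$drug_cost > 0)
      10 * setting$intervention$drug_cost else 350

  f <- function(price) {
    ov <- scenario_spec("price", list("intervention.drug_cost" = price))
    run_scenario(setting, ov)$icer_per_qaly - wtp
  }
  f0 <- f(0); f1 <- f(upper)
  if (f0 > 0 || f1 < 0)
    stop("no threshold price in [0, ", format(upper),
         "] for WTP ", format(wtp), call. = FALSE)
  stats::uniroot(f, c(0, upper), tol = tol)$root
}
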