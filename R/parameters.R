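#' Per-arm transition probabilities and drug cost
#'
#' Bundles the monthly transition probabilities of one treatment arm together
#' with its monthly drug acquisition cost. All probabilities are *monthly*
#' (per one-month model cycle); hospitalization for heart failure (HHF) is a
#' transient within-cycle event, cardiovascular (CV) and non-cardiovascular
#' death are absorbing exits.
#'
#' @param name Arm label, e.g. `"empagliflozin"`.
#' @param p_hhf Monthly probability of hospitalization for heart failure.
#' @param p_cvd Monthly probability of cardiovascular death.
#' @param p_ncd Monthly probability of non-cardiovascular death.
#' @param drug_cost Drug acquisition cost, US$ per month (0 for a comparator
#'   arm whose background therapy cost is carried in the chronic-care cost).
#' @return An object of class `arm_parameters`.
#' @examples
#' arm_parameters("empagliflozin", 0.008811915, 0.006589325, 0.002113141, 35)
#' @export
arm_parameters <- function(name, p_hhf, p_cvd, p_ncd, drug_cost) {
  x <- structure(
    list(name = as.character(name), p_hhf = p_hhf, p_cvd = p_cvd,
         p_ncd = p_ncd, drug_cost = drug_cost),
    class = "arm_parameters"
  )
  validate_arm_parameters(x)
  x
}

validate_arm_parameters <- function(x) {
  for (f in c("p_hhf", "p_cvd", "p_ncd")) {
    p <- x[[f]]
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p >= 1)
      stop("arm '", x$name, "': ", f, " must be a probability in [0, 1), got ",
           format(p), call. = FALSE)
  }
  if (x$p_cvd + x$p_ncd >= 1)
    stop("arm '", x$name, "': p_cvd + p_ncd must be < 1", call. = FALSE)
  if (!is.numeric(x$drug_cost) || is.na(x$drug_cost) || x$drug_cost < 0)
    stop("arm '", x$name, "': drug_cost must be >= 0", call. = FALSE)
  invisible(x)
}

#' @export
print.arm_parameters <- function(x, ...) {
  cat(sprintf("<arm_parameters> %s\n", x$name))
  cat(sprintf("  p_hhf = %.6g  p_cvd = %.6g  p_ncd = %.6g (monthly)\n",
              x$p_hhf, x$p_cvd, x$p_ncd))
  cat(sprintf("  drug cost = %.2f US$/month\n", x$drug_cost))
  invisible(x)
}

#' Utilities, costs and discounting inputs
#'
#' Economic inputs shared by both treatment arms: the stable-HF utility (on an
#' annual 0-1 scale), the per-year-of-age utility decrement, the disutility of
#' a hospitalization month, chronic monthly care cost, one-off event costs,
#' and the annual discount rate.
#'
#' @param u_stable Utility of stable heart failure (annual scale, 0-1).
#' @param u_age_decrement Utility change per year of age (<= 0).
#' @param u_hhf_decrement Utility decrement applied during a hospitalization
#'   month (<= 0).
#' @param cost_stable Chronic HF care cost, US$ per month.
#' @param cost_hhf One-off cost per HHF event, US$.
#' @param cost_pre_cvd One-off cost in the cycle of cardiovascular death, US$.
#' @param cost_pre_ncd One-off cost in the cycle of non-cardiovascular death,
#'   US$.
#' @param discount_rate_annual Annual discount rate applied to costs and
#'   effects (fraction, e.g. 0.03).
#' @return An object of class `economic_inputs`.
#' @export
economic_inputs <- function(u_stable, u_age_decrement, u_hhf_decrement,
                            cost_stable, cost_hhf, cost_pre_cvd, cost_pre_ncd,
                            discount_rate_annual = 0.03) {
  x <- structure(
    list(u_stable = u_stable, u_age_decrement = u_age_decrement,
         u_hhf_decrement = u_hhf_decrement, cost_stable = cost_stable,
         cost_hhf = cost_hhf, cost_pre_cvd = cost_pre_cvd,
         cost_pre_ncd = cost_pre_ncd,
         discount_rate_annual = discount_rate_annual),
    class = "economic_inputs"
  )
  validate_economic_inputs(x)
  x
}

validate_economic_inputs <- function(x) {
  if (x$u_stable < 0 || x$u_stable > 1)
    stop("u_stable must be in [0, 1]", call. = FALSE)
  if (x$u_age_decrement > 0)
    stop("u_age_decrement must be <= 0", call. = FALSE)
  if (x$u_hhf_decrement > 0)
    stop("u_hhf_decrement must be <= 0", call. = FALSE)
  if (x$u_stable + x$u_hhf_decrement < 0)
    stop("u_stable + u_hhf_decrement must be >= 0", call. = FALSE)
  for (f in c("cost_stable", "cost_hhf", "cost_pre_cvd", "cost_pre_ncd")) {
    if (!is.numeric(x[[f]]) || is.na(x[[f]]) || x[[f]] < 0)
      stop(f, " must be >= 0", call. = FALSE)
  }
  if (x$discount_rate_annual < 0)
    stop("discount_rate_annual must be >= 0", call. = FALSE)
  invisible(x)
}

#' Convert an event proportion over a follow-up window to a monthly probability
#'
#' Assuming a constant monthly event hazard, a proportion `p_followup` of
#' patients with at least one event over `followup_months` months corresponds
#' to a monthly event probability `1 - (1 - p_followup)^(1/followup_months)`.
#' This is the derivation used to turn trial event proportions (median 16
#' months of follow-up) into the model's monthly transition probabilities.
#'
#' @param p_followup Proportion of patients with the event over the follow-up
#'   window, in `[0, 1)`.
#' @param followup_months Length of the follow-up window in months (>= 1).
#' @return Monthly event probability.
#' @seealso [monthly_prob_to_proportion()] for the inverse.
#' @examples
#' proportion_to_monthly_prob(0.183, 16) # ~0.01257/month
#' @export
proportion_to_monthly_prob <- function(p_followup, followup_months) {
  if (any(p_followup < 0) || any(p_followup >= 1))
    stop("p_followup must be in [0, 1): a proportion of 1 implies infinite hazard",
         call. = FALSE)
  if (any(followup_months < 1))
    stop("followup_months must be >= 1", call. = FALSE)
  1 - (1 - p_followup)^(1 / followup_months)
}

#' Inverse of [proportion_to_monthly_prob()]
#'
#' @param p_monthly Monthly event probability in `[0, 1)`.
#' @param followup_months Follow-up window in months.
#' @return Proportion of patients with at least one event over the window.
#' @export
monthly_prob_to_proportion <- function(p_monthly, followup_months) {
  if (any(p_monthly < 0) || any(p_monthly >= 1))
    stop("p_monthly must be in [0, 1)", call. = FALSE)
  1 - (1 - p_monthly)^followup_months
}

#' Method-of-moments beta distribution fit
#'
#' Returns the beta shape parameters whose mean and standard deviation equal
#' the supplied values. Used to parameterise probabilistic sensitivity
#' analysis distributions for transition probabilities and utilities from the
#' mean and standard-error columns of the input table.
#'
#' @param mean Mean on the native (0, 1) scale.
#' @param se Standard error (> 0) on the native scale.
#' @return A list with elements `shape1` and `shape2`.
#' @examples
#' fit_beta(0.770, 0.016)
#' @export
fit_beta <- function(mean, se) {
  if (!is.numeric(mean) || mean <= 0 || mean >= 1)
    stop("fit_beta: mean must be in (0, 1)", call. = FALSE)
  if (!is.numeric(se) || se <= 0)
    stop("fit_beta: se must be > 0", call. = FALSE)
  if (se^2 >= mean * (1 - mean))
    stop("fit_beta: se^2 >= mean*(1-mean); beta moments are infeasible",
         call. = FALSE)
  nu <- mean * (1 - mean) / se^2 - 1
  list(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Method-of-moments gamma distribution fit
#'
#' Returns the gamma shape and scale whose mean and standard deviation equal
#' the supplied values: `shape = (mean/se)^2`, `scale = se^2/mean`. Used for
#' cost parameters in probabilistic sensitivity analysis (costs cannot be
#' negative).
#'
#' @param mean Mean (> 0).
#' @param se Standard error (> 0).
#' @return A list with elements `shape` and `scale`.
#' @examples
#' fit_gamma(450, 225) # shape 4, scale 112.5
#' @export
fit_gamma <- function(mean, se) {
  if (!is.numeric(mean) || mean <= 0)
    stop("fit_gamma: mean must be > 0", call. = FALSE)
  if (!is.numeric(se) || se <= 0)
    stop("fit_gamma: se must be > 0", call. = FALSE)
  list(shape = (mean / se)^2, scale = se^2 / mean)
}
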