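#' Configuration for a synthetic two-arm trial
#'
#' Describes a two-arm trial with constant monthly event hazards over a fixed
#' follow-up, emulating the statistical structure from which the model's
#' transition probabilities are derived: per-patient monthly Bernoulli events,
#' summarised as the proportion of patients with at least one event of each
#' type over follow-up.
#'
#' @param n_per_arm Patients per arm (>= 1).
#' @param followup Follow-up length in months (default 16).
#' @param intervention,comparator [arm_parameters()] giving each arm's true
#'   monthly event probabilities (drug cost is carried through to
#'   [derive_arm_parameters()]).
#' @param seed Integer seed.
#' @return An object of class `trial_sim_config`.
#' @export
trial_sim_config <- function(n_per_arm, followup = 16,
                             intervention, comparator, seed = 1) {
  stopifnot(n_per_arm >= 1, followup >= 1)
  validate_arm_parameters(intervention)
  validate_arm_parameters(comparator)
  structure(list(n_per_arm = as.integer(n_per_arm),
                 followup = as.integer(followup),
                 intervention = intervention, comparator = comparator,
                 seed = as.integer(seed)),
            class = "trial_sim_config")
}

# first-occurrence month of a monthly-Bernoulli event; Inf if it never fires
first_event_month <- function(n, p) {
  if (p <= 0) return(rep(Inf, n))
  stats::rgeom(n, p) + 1
}

#' Simulate a synthetic two-arm trial
#'
#' For each patient and event type (HHF, cardiovascular death,
#' non-cardiovascular death), draws the first-occurrence month under
#' independent monthly Bernoulli hazards and counts the patients whose first
#' occurrence falls within follow-up. Each event type is counted against its
#' own latent first-occurrence time (marginal counting), so the expected
#' proportion for an event with monthly probability `p` is exactly
#' `1 - (1 - p)^followup` — the derivation formula's inverse — for every event
#' type. Deterministic under the config's seed.
#'
#' @param config A [trial_sim_config()].
#' @return An object of class `trial_summary`: per-arm counts and proportions
#'   of patients with >= 1 event of each type, plus `n_per_arm` and
#'   `followup`.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "trial_sim_config"))
  set.seed(config$seed)
  n <- config$n_per_arm
  fu <- config$followup
  arm_summary <- function(arm) {
    counts <- vapply(c(p_hhf = arm$p_hhf, p_cvd = arm$p_cvd, p_ncd = arm$p_ncd),
                     function(p) sum(first_event_month(n, p) <= fu),
                     numeric(1))
    names(counts) <- c("hhf", "cvd", "ncd")
    list(name = arm$name, drug_cost = arm$drug_cost,
         counts = counts, proportions = counts / n)
  }
  structure(list(intervention = arm_summary(config$intervention),
                 comparator = arm_summary(config$comparator),
                 n_per_arm = n, followup = fu, seed = config$seed),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("<trial_summary> %d patients/arm, %d-month follow-up\n",
              x$n_per_arm, x$followup))
  for (a in list(x$intervention, x$comparator))
    cat(sprintf("  %-18s HHF %.3f  CV death %.3f  non-CV death %.3f\n",
                a$name, a$proportions["hhf"], a$proportions["cvd"],
                a$proportions["ncd"]))
  invisible(x)
}

#' Derive monthly arm parameters from trial summary proportions
#'
#' Applies [proportion_to_monthly_prob()] to each event proportion of one arm
#' of a [simulate_trial()] summary, attaching the arm's monthly drug cost.
#'
#' @param summary A `trial_summary`.
#' @param arm `"intervention"` or `"comparator"`.
#' @param followup Follow-up months (defaults to the summary's).
#' @param drug_cost Monthly drug cost (defaults to the one carried in the
#'   summary).
#' @return An [arm_parameters()] object.
#' @export
derive_arm_parameters <- function(summary, arm = c("intervention", "comparator"),
                                  followup = summary$followup,
                                  drug_cost = NULL) {
  stopifnot(inherits(summary, "trial_summary"))
  arm <- match.arg(arm)
  a <- summary[[arm]]
  if (any(a$proportions >= 1))
    stop("cannot derive a monthly probability from a proportion of 1",
         call. = FALSE)
  arm_parameters(
    name = a$name,
    p_hhf = proportion_to_monthly_prob(a$proportions[["hhf"]], followup),
    p_cvd = proportion_to_monthly_prob(a$proportions[["cvd"]], followup),
    p_ncd = proportion_to_monthly_prob(a$proportions[["ncd"]], followup),
    drug_cost = if (is.null(drug_cost)) a$drug_cost else drug_cost
  )
}

#' Fabricate a plausible country setting for multi-country runner tests
#'
#' Produces a synthetic country configuration from the Taiwan template: all
#' costs scaled by `cost_scale`, utilities jittered within their valid ranges,
#' and willingness-to-pay thresholds scaled with costs. With `cost_scale = 1`
#' and `jitter = 0` this is the Taiwan setting itself. The output always
#' passes [country_setting()] validation and survives a
#' [save_setting()]/[load_setting()] round trip.
#'
#' @param seed Integer seed for the jitter.
#' @param cost_scale Positive multiplier applied to every cost and the WTP
#'   thresholds.
#' @param jitter Relative jitter on utilities (default 0.02; 0 disables).
#' @param label Setting label (default derived from the seed).
#' @return A [country_setting()].
#' @export
fabricate_country <- function(seed = 1, cost_scale = 1, jitter = 0.02,
                              label = sprintf("synthetic-%d", seed)) {
  stopifnot(cost_scale > 0, jitter >= 0, jitter < 0.5)
  set.seed(seed)
  tw <- taiwan_setting()
  jit <- function(x) if (jitter == 0) x else x * stats::runif(1, 1 - jitter, 1 + jitter)
  u_st <- min(jit(tw$econ$u_stable), 1)
  econ <- economic_inputs(
    u_stable = u_st,
    u_age_decrement = jit(tw$econ$u_age_decrement),
    u_hhf_decrement = max(jit(tw$econ$u_hhf_decrement), -u_st),
    cost_stable = tw$econ$cost_stable * cost_scale,
    cost_hhf = tw$econ$cost_hhf * cost_scale,
    cost_pre_cvd = tw$econ$cost_pre_cvd * cost_scale,
    cost_pre_ncd = tw$econ$cost_pre_ncd * cost_scale,
    discount_rate_annual = tw$econ$discount_rate_annual
  )
  int <- tw$intervention
  int$drug_cost <- int$drug_cost * cost_scale
  se <- tw$se
  se$intervention$drug_cost <- se$intervention$drug_cost * cost_scale
  for (f in c("cost_stable", "cost_hhf", "cost_pre_cvd", "cost_pre_ncd"))
    se$econ[[f]] <- se$econ[[f]] * cost_scale
  country_setting(label, int, tw$comparator, econ, tw$settings,
                  wtp_1x = tw$wtp_1x * cost_scale,
                  wtp_3x = tw$wtp_3x * cost_scale, se = se)
}
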