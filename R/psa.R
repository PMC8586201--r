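#' Parameter distribution for probabilistic sensitivity analysis
#'
#' @param family `"beta"`, `"gamma"`, or `"fixed"`. Beta is used for
#'   probabilities and utilities (values bounded in (0, 1); a negative-mean
#'   utility decrement is sampled as beta on its magnitude and negated), gamma
#'   for costs (non-negative).
#' @param mean Mean on the native scale (may be negative for a decrement).
#' @param se Standard error on the native scale (ignored for `"fixed"`).
#' @return An object of class `param_dist`.
#' @export
param_dist <- function(family = c("beta", "gamma", "fixed"), mean, se = 0) {
  family <- match.arg(family)
  if (family == "beta") {
    m <- abs(mean)
    if (m <= 0 || m >= 1) stop("beta requires |mean| in (0, 1)", call. = FALSE)
    fit_beta(m, se)  # validates feasibility at setup, not draw, time
  }
  if (family == "gamma") {
    if (abs(mean) <= 0) stop("gamma requires mean != 0", call. = FALSE)
    fit_gamma(abs(mean), se)
  }
  structure(list(family = family, mean = mean, se = se), class = "param_dist")
}

draw_param <- function(dist, n, quantile = NULL) {
  sgn <- if (dist$mean < 0) -1 else 1
  m <- abs(dist$mean)
  switch(dist$family,
    fixed = rep(dist$mean, n),
    beta = {
      sh <- fit_beta(m, dist$se)
      sgn * if (is.null(quantile)) stats::rbeta(n, sh$shape1, sh$shape2)
            else stats::qbeta(quantile, sh$shape1, sh$shape2)
    },
    gamma = {
      sh <- fit_gamma(m, dist$se)
      sgn * if (is.null(quantile)) stats::rgamma(n, sh$shape, scale = sh$scale)
            else stats::qgamma(quantile, sh$shape, scale = sh$scale)
    })
}

#' Default PSA distribution map for a setting
#'
#' Builds the distribution of every sampled parameter from the setting's
#' stored standard errors (`setting$se`): beta for transition probabilities
#' and utilities, gamma for costs. Parameters without a stored standard error
#' (or with `se = 0`) are held fixed. Keys are dotted parameter paths as in
#' [scenario_spec()].
#'
#' @param setting A [country_setting()] carrying an `se` block (as
#'   [taiwan_setting()] does).
#' @return Named list of [param_dist()] objects.
#' @export
default_distributions <- function(setting) {
  stopifnot(inherits(setting, "country_setting"))
  se <- setting$se
  get_se <- function(section, field) {
    v <- tryCatch(se[[section]][[field]], error = function(e) NULL)
    if (is.null(v)) 0 else v
  }
  out <- list()
  for (arm in c("intervention", "comparator")) {
    for (f in c("p_hhf", "p_cvd", "p_ncd")) {
      m <- setting[[arm]][[f]]; s <- get_se(arm, f)
      out[[paste0(arm, ".", f)]] <-
        if (s > 0 && m > 0) param_dist("beta", m, s) else param_dist("fixed", m)
    }
    m <- setting[[arm]]$drug_cost; s <- get_se(arm, "drug_cost")
    out[[paste0(arm, ".drug_cost")]] <-
      if (s > 0 && m > 0) param_dist("gamma", m, s) else param_dist("fixed", m)
  }
  beta_fields <- c("u_stable", "u_age_decrement", "u_hhf_decrement")
  gamma_fields <- c("cost_stable", "cost_hhf", "cost_pre_cvd", "cost_pre_ncd")
  for (f in c(beta_fields, gamma_fields)) {
    m <- setting$econ[[f]]; s <- get_se("econ", f)
    fam <- if (f %in% beta_fields) "beta" else "gamma"
    out[[paste0("econ.", f)]] <-
      if (s > 0 && m != 0) param_dist(fam, m, s) else param_dist("fixed", m)
  }
  out[["econ.discount_rate_annual"]] <-
    param_dist("fixed", setting$econ$discount_rate_annual)
  out
}

# one joint draw matrix: n rows, one column per distribution key
draw_matrix <- function(distributions, n, arm_mode) {
  keys <- names(distributions)
  vals <- list()
  pair_fields <- c("p_hhf", "p_cvd", "p_ncd")
  for (key in keys) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    d <- distributions[[key]]
    if (parts[1] == "intervention" && parts[2] %in% pair_fields &&
        arm_mode != "independent") next  # derived from the comparator draw
    vals[[key]] <- draw_param(d, n)
  }
  if (arm_mode != "independent") {
    for (f in pair_fields) {
      ik <- paste0("intervention.", f); ck <- paste0("comparator.", f)
      di <- distributions[[ik]]; dc <- distributions[[ck]]
      vals[[ik]] <- if (arm_mode == "relative_effect") {
        rr <- if (dc$mean > 0) di$mean / dc$mean else 0
        pmin(vals[[ck]] * rr, 1 - 1e-12)
      } else { # shared_quantile: same uniform through each arm's own beta
        u <- if (dc$family == "beta") {
          sh <- fit_beta(dc$mean, dc$se)
          stats::pbeta(vals[[ck]], sh$shape1, sh$shape2)
        } else stats::runif(n)
        draw_param(di, n, quantile = u)
      }
    }
  }
  as.data.frame(vals[keys], check.names = FALSE, optional = TRUE)
}

draw_to_setting <- function(setting, row) {
  s <- setting
  for (key in names(row)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    s[[parts[1]]][[parts[2]]] <- row[[key]]
  }
  country_setting(s$label, s$intervention, s$comparator, s$econ, s$settings,
                  s$wtp_1x, s$wtp_3x, s$se)
}

#' Draw one sampled setting for probabilistic sensitivity analysis
#'
#' One joint draw from the parameter distributions: utilities and costs are
#' shared by both arms; transition probabilities are handled per `arm_mode`.
#' `"relative_effect"` (default) samples the comparator's baseline
#' probabilities and carries the intervention's relative risks over unchanged,
#' preserving the trial's treatment effect; `"shared_quantile"` pushes one
#' uniform quantile through both arms' marginal betas; `"independent"` samples
#' each arm separately (which also randomises the treatment effect itself).
#'
#' @param setting A [country_setting()].
#' @param distributions Distribution map, by default
#'   [default_distributions()]`(setting)`.
#' @param seed Optional integer seed for reproducibility.
#' @param arm_mode How arm probability pairs co-vary (see above).
#' @return A sampled, validated `country_setting`.
#' @export
sample_parameters <- function(setting, distributions = default_distributions(setting),
                              seed = NULL,
                              arm_mode = c("relative_effect", "shared_quantile",
                                           "independent")) {
  arm_mode <- match.arg(arm_mode)
  if (!is.null(seed)) set.seed(seed)
  draw_to_setting(setting, draw_matrix(distributions, 1, arm_mode)[1, , drop = FALSE])
}

# First-order (patient-level) Monte Carlo totals for one arm.
# Each simulated patient draws a death cycle (geometric on the combined
# monthly death probability), a cause (categorical), and a hospitalization
# count over the alive, at-risk window; hospitalization timing within the
# window is integrated analytically (window-mean discount factor), which
# keeps the estimator's expectation identical to the cohort run.
sample_cohort_totals <- function(arm, econ, settings, n_patients) {
  H <- settings$horizon_cycles
  cyc <- seq_len(H)
  df <- discount_factor(cyc, econ$discount_rate_annual, settings$discount_method)
  age_off <- if (settings$age_step == "continuous") (cyc - 1) / 12
             else floor((cyc - 1) / 12)
  u <- pmax(econ$u_stable + econ$u_age_decrement * age_off, 0)
  A <- settings$accrual_months
  S_cost <- cumsum(df * A * (arm$drug_cost + econ$cost_stable))
  S_qaly <- cumsum(df * A * u / 12)
  S_ly <- cumsum(df * A / 12)
  cdf <- cumsum(df)

  k_free <- if (settings$first_cycle_event_free) 1L else 0L
  p_d <- arm$p_cvd + arm$p_ncd
  kd <- if (p_d > 0) k_free + 1L + stats::rgeom(n_patients, p_d)
        else rep(H + 1L, n_patients)
  died <- kd <= H
  kk <- pmin(kd, H)

  cost <- S_cost[kk]
  qaly <- S_qaly[kk]
  ly <- S_ly[kk]
  if (any(died)) {
    is_cv <- stats::runif(n_patients) < (if (p_d > 0) arm$p_cvd / p_d else 0)
    cost[died] <- cost[died] +
      df[kk[died]] * ifelse(is_cv[died], econ$cost_pre_cvd, econ$cost_pre_ncd)
  }
  n_risk <- pmax(kk - k_free, 0L)
  m_hhf <- stats::rbinom(n_patients, n_risk, arm$p_hhf)
  mean_df <- ifelse(n_risk > 0, (cdf[kk] - if (k_free > 0) cdf[k_free] else 0) / pmax(n_risk, 1), 0)
  cost <- cost + m_hhf * mean_df * econ$cost_hhf
  qaly <- qaly + m_hhf * mean_df * econ$u_hhf_decrement / 12

  structure(list(name = arm$name, cost = mean(cost), qaly = mean(qaly),
                 ly = mean(ly)),
            class = "arm_totals")
}

#' Probabilistic sensitivity analysis
#'
#' Runs `n` Monte Carlo iterations. Each iteration draws one joint parameter
#' sample (second-order uncertainty; see [sample_parameters()]) and evaluates
#' the two-arm model. With `n_patients` set (default 1865 per arm, the size of
#' each arm of the source trial population), the evaluation simulates that
#' many individual patients per arm (first-order, patient-level uncertainty);
#' with `n_patients = NULL` each iteration is a deterministic cohort run at
#' the sampled parameters.
#'
#' @param setting A [country_setting()].
#' @param n Number of iterations (default 1000).
#' @param seed Integer seed; the full result is bit-reproducible given
#'   (`seed`, `n`, `n_patients`).
#' @param distributions Distribution map (default
#'   [default_distributions()]`(setting)`).
#' @param arm_mode Arm probability co-variation; see [sample_parameters()].
#' @param n_patients Patients simulated per arm per iteration, or `NULL` for
#'   cohort-expectation evaluation.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve,
#'   US$/QALY (default 0 to 100,000 in steps of 1,000).
#' @return An object of class `psa_result`: list with `draws` (data frame of
#'   `draw`, `d_cost`, `d_qaly`), `ceac` (data frame of `wtp`, `prob_ce`),
#'   `n_draws`, `n_patients`, `seed`.
#' @examples
#' \donttest{
#' psa <- run_psa(taiwan_setting(), n = 200, seed = 1)
#' psa$ceac[psa$ceac$wtp %in% c(25000, 75000), ]
#' }
#' @export
run_psa <- function(setting, n = 1000, seed = 1,
                    distributions = default_distributions(setting),
                    arm_mode = c("relative_effect", "shared_quantile",
                                 "independent"),
                    n_patients = 1865,
                    wtp_grid = seq(0, 100000, by = 1000)) {
  arm_mode <- match.arg(arm_mode)
  stopifnot(n >= 1)
  set.seed(seed)
  draws <- draw_matrix(distributions, n, arm_mode)
  d_cost <- d_qaly <- numeric(n)
  for (i in seq_len(n)) {
    s_i <- draw_to_setting(setting, draws[i, , drop = FALSE])
    res <- if (is.null(n_patients)) {
      run_cea(s_i)
    } else {
      compare(
        sample_cohort_totals(s_i$intervention, s_i$econ, s_i$settings, n_patients),
        sample_cohort_totals(s_i$comparator, s_i$econ, s_i$settings, n_patients)
      )
    }
    d_cost[i] <- res$d_cost
    d_qaly[i] <- res$d_qaly
  }
  out <- structure(
    list(draws = data.frame(draw = seq_len(n), d_cost = d_cost, d_qaly = d_qaly),
         n_draws = n, n_patients = n_patients, seed = seed, ceac = NULL),
    class = "psa_result"
  )
  out$ceac <- ceac(out, wtp_grid)
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with positive
#' net monetary benefit (`d_qaly x wtp - d_cost > 0`).
#'
#' @param result A `psa_result` from [run_psa()].
#' @param wtp_grid Non-empty vector of WTP values (>= 0).
#' @return Data frame with columns `wtp` and `prob_ce`.
#' @export
ceac <- function(result, wtp_grid = seq(0, 100000, by = 1000)) {
  stopifnot(inherits(result, "psa_result"), length(wtp_grid) >= 1,
            all(wtp_grid >= 0))
  d <- result$draws
  prob <- vapply(wtp_grid,
                 function(w) mean(d$d_qaly * w - d$d_cost > 0),
                 numeric(1))
  data.frame(wtp = wtp_grid, prob_ce = prob)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (seed %s, %s)\n", x$n_draws,
              format(x$seed),
              if (is.null(x$n_patients)) "cohort evaluation"
              else sprintf("%d patients/arm", x$n_patients)))
  cat(sprintf("  mean increments: %+.0f US$, %+.4f QALY\n",
              mean(x$draws$d_cost), mean(x$draws$d_qaly)))
  for (w in c(25000, 75000)) {
    i <- which(x$ceac$wtp == w)
    if (length(i))
      cat(sprintf("  P(cost-effective at %s US$/QALY) = %.1f%%\n",
                  format(w, big.mark = ","), 100 * x$ceac$prob_ce[i]))
  }
  invisible(x)
}
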