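---
title: "Model structure, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfcea)
```

## The decision problem

`hfcea` evaluates adding empagliflozin (10 mg once daily) to guideline-directed
standard therapy in heart failure with reduced ejection fraction (HFrEF), from
a healthcare system's perspective, against standard therapy alone. The
clinical effect sizes come from a large randomized trial in which ~3,730 HFrEF
patients were followed for a median of 16 months; the economic inputs are
Taiwan national-claims cost estimates (2020 US$) and published utility scores.
The bundled Taiwan configuration (`taiwan_setting()`, also shipped as
`inst/extdata/taiwan_base.yaml`) carries every input with its standard error.

## Cohort model

The model is a monthly-cycle, two-state (stable HF, dead) Markov cohort with
hospitalization for heart failure (HHF) as a *transient within-cycle event*:
hospitalized patients either return to stable HF or die after the one-month
acute stage, so hospitalization is not a persistent state. One month was kept
as the cycle length because the acute stage lasts about one month.

Per cycle, the fraction alive at cycle start experiences HHF, cardiovascular
(CV) death, and non-CV death with constant monthly probabilities; the three
events are treated as independent within the cycle (`alive x p` each). No
precedence rule between HHF and death within a month is imposed: with monthly
probabilities of order 0.01 the overlap terms are O(p²) ≈ 10⁻⁴ of a cycle's
events, far below every other convention's effect. Deaths are removed before
the next cycle; occupancy is evaluated at cycle start. The cohort enters in
stable HF with no clinical events in the first cycle
(`first_cycle_event_free = TRUE`).

Monthly probabilities derive from trial event proportions by the
constant-hazard inversion `p = 1 − (1 − P₁₆)^(1/16)`
(`proportion_to_monthly_prob()`). The bundled monthly values back-convert to
the trial's 16-month proportions (HHF 13.2%/18.3%, CV death 10.0%/10.8%,
non-CV death ≈3.3%/3.4%), which is also how we verified that the "all-cause
death" input row must be read as *non-CV* death: treating it as all-cause
would double-count the CV deaths it already contains.

## Accounting conventions

### Discounting, age, and utilities

* Costs and effects discount at 3%/year; the default factor is
  `(1 + r)^(−(cycle−1)/12)` (cycle 1 undiscounted), with a stepwise annual
  variant (`discount_method = "annual"`). The two differ by <1% on the ICER.
* The age-related utility decrement applies continuously
  (`u(age) = u₀ + δ·(age − 67)`, age advancing 1/12 year per cycle), with an
  annual-step variant. If an extreme decrement drives utility negative it is
  clamped at 0 with a warning.
* The HHF disutility (−0.321) applies for exactly one cycle per event,
  prorated by 1/12, matching the one-month acute stage. Pre-death costs are
  one-off in the cycle of death and cause-specific. Dead states accrue
  nothing.

### State-reward accrual (`accrual_months`)

The one deliberately unusual default. Under strict calendar accounting (one
month of cost/utility/life-time per monthly cycle) the bundled Taiwan inputs
give a base-case ICER of ~17,410 US$/QALY — 15% below the reference value for
these inputs, with every scenario similarly displaced. Back-calculation from
the reference results shows why:

* the reference discounted life expectancy (12.89 LY over a 15-year horizon)
  exceeds the *zero-mortality* bound of calendar accounting (12.12 LY at 3%);
* the reference half-drug-price scenario implies a total drug cost of
  ≈ 35 × 155 discounted person-months, twice the survival curve's person-time;
* the reference 16-month-horizon per-arm costs (15,184/14,232 US$) match
  doubled state accrual to 0.15%, and the reference ΔLY (0.47) is exactly
  twice the survival-curve ΔLY —

while terminal mortality (79.3%/81.4%) and hospitalization counts (803/1,099
per 1,000) match the survival curve at face value. The generating engine is
therefore equivalent to transitions on a half-month grid (per-sub-cycle
probability p/2) with *monthly-sized* rewards left unhalved: state rewards
accrue at twice the calendar rate, one-off event rewards accrue once. `hfcea`
reproduces this with `model_settings(accrual_months = 2)` (the default, so
that results computed from the bundled inputs are comparable with their
source), and offers `accrual_months = 1` for calendar-time accounting. Under
the default, the base case lands within ~2.5% of the reference ICER and most
scenarios within 5%. One consequence: discounted life-years can exceed the
horizon's calendar years (e.g. QALYs of 1.86 over a 16-month run), as they do
in the reference results.

### Two reference quantities we cannot reproduce

Two printed reference values are internally inconsistent with the rest of
their own table, and the package makes no attempt to match them:

* **16-month-horizon ICER (91,617)**: the row's per-arm costs and ΔCost
  reproduce to <4%, but its implied ΔQALY (0.0104) exceeds what any occupancy
  or event-free convention yields (≤0.0093) even though the base-case and
  equal-CV-mortality ΔQALYs match to three decimals. The model gives
  ≈105,000.
* **Threshold price at WTP 20,000 (31.5 US$/month)**: the reference threshold
  row has a consistent internal slope (~430 US$/QALY per US$ of monthly
  price, matching the half-price scenario) but an intercept implying a base
  ICER of ~21,500 rather than the printed 20,508. Any model consistent with
  the printed base case solves to ≈33.8–35 US$. The solver here returns
  ≈35.0.

## Sensitivity analyses

`one_way_sa()` perturbs each parameter ±10% (the plausible range), holding
others at base: arm-specific parameters per arm, shared economic parameters
once for both arms. Values perturbed out of range are clamped to the boundary
with a message. CV-death risk dominates the tornado, followed by non-CV death
risk — as expected, since the arms' survival gap drives the QALY increment.
The utility bars perturb the annual utility value (not its monthly proration);
either reading only rescales the same bar.

`run_scenario()` applies dotted-path overrides purely (the base setting is
never mutated); equal-risk scenarios set the intervention probability *equal
to the comparator's value*, not the midpoint. `threshold_drug_price()`
exploits that the ICER is affine and strictly increasing in the drug price
(slope = discounted intervention person-time / ΔQALY) and solves by
`stats::uniroot` to 0.01 US$.

Adverse events (`adverse_event()`, `run_with_adverse_events()`) enter as
independent expected-value add-ons — per cycle, `alive x p x cost` and
`alive x p x disutility/12` — rather than as a distinct state, since only the
aggregate impact of the adverse-event model variant is specified; its exact
per-event parameter values are not distributed with the package.

## Probabilistic sensitivity analysis

Each of the default 1,000 iterations draws one joint parameter sample and
evaluates the model. Distribution families follow standard practice: beta for
probabilities and utilities (decrements sampled as beta on the magnitude and
negated), gamma for costs. Utilities and shared costs are drawn once per
iteration for both arms.

Two design choices deserve explanation:

* **Arm probability correlation.** The arm difference in monthly CV death
  (0.00054) is a quarter of its own standard error (~0.0019). Sampling the
  two arms independently therefore randomises the *treatment effect itself*
  far beyond the trial's uncertainty about the relative effect, and drives
  P(ΔQALY > 0) to ~0.55 — the intervention's effect becomes a coin flip,
  which contradicts both the trial and the reference acceptability curve. The
  default `arm_mode = "relative_effect"` samples the comparator's baseline
  probabilities from their betas and carries the intervention's relative
  risks over unchanged; `"shared_quantile"` and `"independent"` are available
  for comparison.
* **First-order patient sampling.** The reference procedure randomly sampled
  subjects "with equivalent characteristics as the trial population" in each
  iteration. `run_psa()` therefore simulates `n_patients = 1865` individual
  patients per arm (the trial's arm size) per iteration: per patient a death
  cycle (geometric), a cause (categorical), and an HHF count over the alive
  window (binomial; event timing within the window is integrated analytically
  with the window-mean discount factor, which keeps the estimator unbiased
  for the cohort expectation). Set `n_patients = NULL` for pure second-order
  PSA. With the defaults and seed 1, P(cost-effective) is ≈66% at WTP 25,000
  and ≈92% at 75,000, against reference values of 63.4% and 93.7%; the
  remaining ~2–3 points reflect the reference engine's unrecoverable
  patient-sampling details.

Because the model is nonlinear in the transition probabilities, the PSA mean
of the increments sits a small Jensen gap (~2%) away from the deterministic
run at the distribution means; with probabilities held fixed the gap vanishes
(costs and utilities enter linearly), which is how the test suite separates
Monte-Carlo convergence from nonlinearity.

All randomness flows from explicit seeds; a `(seed, n, n_patients)` triple
reproduces a PSA bit-identically.

## Synthetic trial generator

`simulate_trial()` emulates the statistical structure the probability
derivation assumes: per patient and event type, first-occurrence times under
independent monthly Bernoulli hazards over a 16-month follow-up, summarised as
the proportion of patients with ≥1 event. Each event type is counted against
its own latent first-occurrence time (*marginal counting*). The alternative —
censoring event counts at the patient's death — biases the non-CV-death
proportion by ~5% and the HHF proportion by ~8% relative (competing risks),
which would break the exact self-consistency between the generator and
`proportion_to_monthly_prob()`; marginal counting keeps the expected
proportion at exactly `1 − (1 − p)^16` for every event type, so parameter
recovery is unbiased. What the generator deliberately does not emulate:
randomisation imbalance, covariates, time-varying hazards, recurrent-event
correlation, or dropout — so passing recovery tests demonstrate the
derivation pipeline, not robustness to real-trial complications.

`fabricate_country()` produces valid synthetic country configurations (Taiwan
template with scaled costs/thresholds and jittered utilities) for exercising
the multi-country batch runner; they are labelled synthetic and claim no
real-country values.

## Test problem sizes

The suite uses sizes chosen to keep each oracle sharp at interactive runtimes:
1,000-draw property loops for mass conservation and moment round-trips,
50,000–100,000 patients for synthetic-trial recovery (3 propagated binomial
SEs), 2,000 cohort-mode draws for PSA convergence, and the full n = 1,000,
1,865-patients/arm PSA for the acceptability-curve checks.

## Known limitations

* Constant transition probabilities: no age- or time-varying hazards, no
  post-hospitalization risk elevation (uniform death risk in the HHF month).
* Direct medical costs only; no societal or indirect costs, no EVPI/EVPPI.
* Country configs for settings other than Taiwan are schema-supported but not
  shipped with claimed values.
* The default accrual convention is the reference engine's, not calendar
  time; analysts making de-novo projections should consider
  `accrual_months = 1` and report which convention they used.
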