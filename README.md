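# hfcea

A Markov cohort cost-effectiveness model for **add-on empagliflozin versus
standard therapy alone in heart failure with reduced ejection fraction
(HFrEF)**, from a healthcare system's perspective. The package is aimed at
health-economics analysts who want to reproduce, probe, or re-parameterise the
Taiwan/Asia-Pacific evaluation of empagliflozin 10 mg once daily: base-case
incremental cost-effectiveness, tornado and scenario sensitivity analyses, a
threshold drug-price solver, probabilistic sensitivity analysis (PSA) with
cost-effectiveness acceptability curves (CEAC), a country-configuration schema
for multi-country runs, and a synthetic two-arm trial generator that exercises
the transition-probability derivation end to end.

## The model

A cohort of stable HFrEF patients (start age 67) is simulated over monthly
cycles for 15 years (180 cycles). Each month, a patient in stable heart
failure may be hospitalized for heart failure (HHF, a transient one-month
acute event after which survivors return to stable HF), die of cardiovascular
(CV) cause, or die of non-CV cause, with constant monthly probabilities
*p*<sub>HHF</sub>, *p*<sub>CV</sub>, *p*<sub>nCV</sub> per arm. Monthly
probabilities derive from trial event proportions over a median 16-month
follow-up under constant hazards:

```
p_monthly = 1 − (1 − p_16m)^(1/16)
```

The first cycle is event-free. Per cycle, the model accrues for the alive
fraction the drug and chronic-care costs and the age-adjusted utility
u(age) = u₀ + δ·(age − 67), plus one-off rewards per event: the HHF cost and
disutility, and cause-specific pre-death costs. Costs and effects are
discounted at 3%/year. Then

```
ICER = (C_empa − C_std) / (E_empa − E_std)      E in QALYs or life-years
NMB(λ) = ΔE·λ − ΔC                              λ = willingness to pay
```

State rewards accrue, by default, over **two months of reward time per
monthly cycle** (`model_settings(accrual_months = 2)`), the accounting
convention of the reference analysis the bundled Taiwan inputs come from; set
`accrual_months = 1` for strict calendar-time accounting. The methods
vignette (`vignettes/model-methods.Rmd`) derives this convention from the
reference results and documents every other convention flag (discount
anchoring, half-cycle correction, age stepping).

The PSA samples second-order parameter uncertainty (beta distributions for
probabilities and utilities, gamma for costs, baseline-arm sampling with
preserved relative treatment effects) and first-order patient-level
variability (1,865 simulated patients per arm — the trial's arm size — per
iteration), over 1,000 iterations by default.

## Worked example

```r
library(hfcea)

tw  <- taiwan_setting()   # bundled Table-of-inputs for the Taiwan setting
res <- run_cea(tw)
res
#> <econ_result>
#>   empagliflozin        cost      80408  QALY   9.947  LY  13.081
#>   standard therapy     cost      73199  QALY   9.587  LY  12.613
#>   incremental: +7208 US$, +0.3607 QALY, +0.4674 LY
#>   ICER: 19986 US$/QALY, 15421 US$/LY
```

Adding empagliflozin costs US$7,208 more per patient over 15 years and gains
0.36 QALYs, i.e. about US$19,986 per QALY gained — under the Taiwan
willingness-to-pay threshold of US$25,000 (1x GDP per capita), so the add-on
is very cost-effective there (`net_monetary_benefit(res, 25000)` ≈ +US$1,809
per patient).

```r
run_cohort(tw$comparator, tw$settings)
#> <cohort_trace> arm 'standard therapy', 180 monthly cycles
#>   surviving fraction at horizon: 0.1875 (mortality 81.3%)
#>   per 1,000 patients: 1097 HHF, 622 CV deaths, 190 non-CV deaths
```

The intervention arm's trace shows 79.1% mortality and 801 HHF per 1,000
patients: roughly 296 hospitalizations averted per 1,000 treated. Sensitivity
tooling:

```r
head(one_way_sa(tw), 2)                      # tornado: CV death risk dominates
run_scenario(tw, taiwan_scenarios()$half_drug_cost)  # ICER ~12,369
threshold_drug_price(tw, wtp = 25000)        # ~46.5 US$/month
psa <- run_psa(tw, n = 1000, seed = 1)       # ~66% CE at 25k, ~92% at 75k
```

A command-line wrapper with the same capabilities ships in
`inst/cli/hfcea.R` (subcommands `base`, `tornado`, `scenario`, `psa`,
`threshold`, `batch`, `simulate`; every run writes a provenance manifest).

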