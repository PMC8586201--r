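Package: hfcea
Title: Markov Cohort Cost-Effectiveness Model for Add-On Therapy in Heart
    Failure with Reduced Ejection Fraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A monthly-cycle Markov cohort model for the cost-effectiveness of
    add-on empagliflozin versus standard therapy alone in heart failure with
    reduced ejection fraction (HFrEF), from a healthcare system's perspective.
    Computes discounted lifetime costs, life-years and quality-adjusted
    life-years per treatment arm and incremental cost-effectiveness ratios;
    provides one-way (tornado) and scenario sensitivity analyses, an
    adverse-event model extension, a threshold drug-price solver, and
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves. Ships a fully parameterised Taiwan setting and a synthetic
    two-arm trial generator for end-to-end testing of the probability
    derivation pipeline, plus a country-level configuration schema for
    multi-country scenario analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
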