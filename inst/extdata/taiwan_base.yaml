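# hfcea country-setting config, schema version 1.
# Currency is always US$ (2020); transition probabilities are always monthly.
# Sections: arms (exactly intervention + comparator), econ, settings, wtp,
# and an optional se block of standard errors used to parameterise PSA
# distributions (beta for probabilities/utilities, gamma for costs).
schema_version: 1
label: Taiwan
currency: USD
arms:
  intervention:
    name: empagliflozin
    p_hhf: 0.008811915
    p_cvd: 0.006589325
    p_ncd: 0.002113141
    drug_cost: 35.0
  comparator:
    name: standard therapy
    p_hhf: 0.012566527
    p_cvd: 0.007131185
    p_ncd: 0.002177683
    drug_cost: 0.0
econ:
  u_stable: 0.770
  u_age_decrement: -0.0016
  u_hhf_decrement: -0.321
  cost_stable: 450.0
  cost_hhf: 2887.0
  cost_pre_cvd: 3430.0
  cost_pre_ncd: 3390.0
  discount_rate_annual: 0.03
settings:
  start_age: 67
  horizon_cycles: 180
  first_cycle_event_free: true
  half_cycle_correction: false
  accrual_months: 2
  discount_method: monthly
  age_step: continuous
wtp:
  wtp_1x: 25000
  wtp_3x: 75000
se:
  intervention:
    p_hhf: 0.002165244
    p_cvd: 0.00187447
    p_ncd: 0.001063894
    drug_cost: 17.5
  comparator:
    p_hhf: 0.002578038
    p_cvd: 0.001947398
    p_ncd: 0.001078827
    drug_cost: 0.0
  econ:
    u_stable: 0.016
    u_age_decrement: 0.0001
    u_hhf_decrement: 0.02
    cost_stable: 225.0
    cost_hhf: 1443.5
    cost_pre_cvd: 1715.0
    cost_pre_ncd: 1695.0
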