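p_fn_cycle1: 0.364
rr_cycle2plus: 0.46
rr_history: 2.4
p_fn_death: 0.036
p_rdi_low_base: 0.247
or_rdi_low: 1.58
hr_rdi_low: 1.73
u_chemo: 0.78
u_fn_decrement: 0.36
u_surv_1_5: 0.84
u_surv_5plus: 0.91
cost_fn_event: 8287.0
los_fn: 10.53
annual_bc_mortality: 0.0202
bc_mortality_years: 10.0
discount_rate: 0.03
wtp: 976914.0
start_age: 56.0
n_cycles: 6.0
cycle_days: 21.0
age_cap: 110.0
year_days: 365.25
discount_chemo_qalys: no
drugs:
- drug: filgrastim
  rr_cycles_1_2: 0.64
  rr_cycles_3plus: 0.575
  price: 1673.0
  injections_per_cycle: 4.0
  efficacy_source: filgrastim
- drug: lenograstim
  rr_cycles_1_2: 0.452
  rr_cycles_3plus: 0.609
  price: 1674.0
  injections_per_cycle: 4.0
  efficacy_source: lenograstim
- drug: pegfilgrastim
  rr_cycles_1_2: 0.334
  rr_cycles_3plus: 0.334
  price: 16626.0
  injections_per_cycle: 1.0
  efficacy_source: pegfilgrastim
- drug: filgrastim_biosimilar
  rr_cycles_1_2: 0.64
  rr_cycles_3plus: 0.575
  price: 1559.0
  injections_per_cycle: 4.0
  efficacy_source: filgrastim
- drug: pegfilgrastim_biosimilar
  rr_cycles_1_2: 0.334
  rr_cycles_3plus: 0.334
  price: 14457.0
  injections_per_cycle: 1.0
  efficacy_source: pegfilgrastim
ranges:
  p_fn_cycle1:
  - 0.293
  - 0.436
  rr_cycle2plus:
  - 0.4203
  - 0.5034
  rr_history:
  - 2.2
  - 2.6
  p_fn_death:
  - 0.029
  - 0.043
  rr_filgrastim_cycles_1_2:
  - 0.5077
  - 0.8076
  rr_filgrastim_cycles_3plus:
  - 0.4477
  - 0.7379
  rr_lenograstim_cycles_1_2:
  - 0.2767
  - 0.7393
  rr_lenograstim_cycles_3plus:
  - 0.3944
  - 0.9398
  rr_pegfilgrastim:
  - 0.2097
  - 0.5319
  p_rdi_low_base:
  - 0.149
  - 0.345
  or_rdi_low:
  - 1.2
  - 2.1
  hr_rdi_low:
  - 1.17
  - 2.55
  u_chemo:
  - 0.728
  - 0.832
  u_fn_decrement:
  - 0.289
  - 0.431
  u_surv_1_5:
  - 0.791
  - 0.889
  u_surv_5plus:
  - 0.893
  - 0.927
  price_pegfilgrastim:
  - 13301.0
  - 16626.0
  price_filgrastim:
  - 1338.0
  - 1673.0
  price_lenograstim:
  - 1339.0
  - 1674.0
  cost_fn_event:
  - 6630.0
  - 9944.0
  los_fn:
  - 7.39
  - 13.67
  discount_rate:
  - 0.0
  - 0.05
dist_family:
  p_fn_cycle1: beta
  rr_cycle2plus: log-normal
  rr_history: log-normal
  p_fn_death: beta
  rr_filgrastim_cycles_1_2: log-normal
  rr_filgrastim_cycles_3plus: log-normal
  rr_lenograstim_cycles_1_2: log-normal
  rr_lenograstim_cycles_3plus: log-normal
  rr_pegfilgrastim: log-normal
  p_rdi_low_base: beta
  or_rdi_low: log-normal
  hr_rdi_low: log-normal
  u_chemo: beta
  u_fn_decrement: beta
  u_surv_1_5: beta
  u_surv_5plus: beta
  price_pegfilgrastim: fixed
  price_filgrastim: fixed
  price_lenograstim: fixed
  cost_fn_event: gamma
  los_fn: gamma
  discount_rate: fixed
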