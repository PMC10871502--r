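country: us
currency: USD
start_age: 68.0
horizon_years: 20.0
cycle_length_years: 0.25
wtp: 100000.0
mrs_month3:
  tirofiban:
  - 0.106
  - 0.185
  - 0.329
  - 0.219
  - 0.106
  - 0.017
  - 0.038
  aspirin:
  - 0.083
  - 0.139
  - 0.342
  - 0.291
  - 0.102
  - 0.016
  - 0.027
state_names:
- mrs0
- mrs1
- mrs2
- mrs3
- mrs4
- mrs5
- mrs6
hr_params:
- hr_mrs0
- hr_mrs1
- hr_mrs2
- hr_mrs3
- hr_mrs4
- hr_mrs5
utility_params:
- u_mrs0
- u_mrs1
- u_mrs2
- u_mrs3
- u_mrs4
- u_mrs5
acute_map:
  acute_mrs0_2:
  - 1
  - 2
  - 3
  acute_mrs3_5:
  - 4
  - 5
  - 6
  acute_death: 7.0
posthosp:
  period: quarterly
  map:
    posthosp_mrs0: 1
    posthosp_mrs1: 2
    posthosp_mrs2: 3
    posthosp_mrs3: 4
    posthosp_mrs4: 5
    posthosp_mrs5: 6
life_table:
  age_start:
  - 68.0
  - 73.0
  - 78.0
  - 83.0
  - 88.0
  - 93.0
  - 98.0
  age_end:
  - 72.0
  - 77.0
  - 82.0
  - 87.0
  - 92.0
  - 97.0
  - 102.0
  annual_death_prob:
  - 0.013
  - 0.02106
  - 0.0341172
  - 0.055269864
  - 0.08953717968
  - 0.1450502310816
  - 0.234981374352192
psa_ess: 579.0
regimen:
  loading_rate_ug_kg_min: 0.4
  loading_minutes: 30.0
  maintenance_rate_ug_kg_min: 0.1
  maintenance_hours: 48.0
sich_exposure_years: 0.25
toggles:
  half_cycle: no
  recurrence_includes_source: yes
  infusion_in_aspirin: no
  recurrence_utility_mode: absolute
  mortality_conversion: annual_per_cycle
  discount_costs: no
  discount_effects: yes
params:
  p_sich_tirofiban:
    base: 0.01
    family: beta
    sd: 0.003
    low: 0.0
    high: 0.01
  p_sich_aspirin:
    base: 0.0
    family: fixed
  p_recurrent_annual:
    base: 0.013
    family: beta
    sd: 0.001
    low: 0.01
    high: 0.015
  p_death_after_recurrence:
    base: 0.19
    family: beta
    sd: 0.051
    low: 0.1
    high: 0.3
  hr_mrs0:
    base: 1.0
    family: lognormal
    sd: 0.05
    low: 1.0
    high: 1.2
    truncate_low: 1.0
  hr_mrs1:
    base: 1.0
    family: lognormal
    sd: 0.05
    low: 1.0
    high: 1.2
    truncate_low: 1.0
  hr_mrs2:
    base: 1.11
    family: lognormal
    sd: 0.103
    low: 1.0
    high: 1.3
    truncate_low: 1.0
  hr_mrs3:
    base: 1.27
    family: lognormal
    sd: 0.125
    low: 1.02
    high: 1.52
    truncate_low: 1.0
  hr_mrs4:
    base: 1.71
    family: lognormal
    sd: 0.17
    low: 1.37
    high: 2.05
    truncate_low: 1.0
  hr_mrs5:
    base: 2.37
    family: lognormal
    sd: 0.235
    low: 1.9
    high: 2.84
    truncate_low: 1.0
  u_mrs0:
    base: 0.85
    family: beta
    sd: 0.051
    low: 0.8
    high: 1.0
  u_mrs1:
    base: 0.8
    family: beta
    sd: 0.038
    low: 0.8
    high: 0.95
  u_mrs2:
    base: 0.7
    family: beta
    sd: 0.055
    low: 0.68
    high: 0.9
  u_mrs3:
    base: 0.51
    family: beta
    sd: 0.05
    low: 0.45
    high: 0.65
  u_mrs4:
    base: 0.3
    family: beta
    sd: 0.075
    low: 0.1
    high: 0.4
  u_mrs5:
    base: 0.15
    family: beta
    sd: 0.08
    low: 0.0
    high: 0.32
  u_recurrence:
    base: 0.31
    family: beta
    sd: 0.033
    low: 0.24
    high: 0.37
  du_sich:
    base: 0.38
    family: beta
    sd: 0.04
    low: 0.3
    high: 0.46
  discount_rate:
    base: 0.03
    family: fixed
    low: 0.0
    high: 0.08
  drug_price_per_mg:
    base: 19.289999999999999
    family: gamma
    sd: 1.93
    low: 9.640000000000001
    high: 38.57
  weight_kg:
    base: 90.0
    family: beta
    sd: 15.0
    low: 60.0
    high: 150.0
    scale_low: 60.0
    scale_high: 150.0
  infusion_first_hour:
    base: 142.550000000000011
    family: gamma
    sd: 14.300000000000001
    low: 100.0
    high: 200.0
  infusion_additional_hour:
    base: 30.68
    family: gamma
    sd: 3.07
    low: 20.0
    high: 40.0
  acute_mrs0_2:
    base: 15561.0
    family: gamma
    sd: 1556.0
    low: 15375.0
    high: 15748.0
  acute_mrs3_5:
    base: 19345.0
    family: gamma
    sd: 1935.0
    low: 19108.0
    high: 19581.0
  acute_death:
    base: 25425.0
    family: gamma
    sd: 2543.0
    low: 24469.0
    high: 26382.0
  cost_sich:
    base: 3678.0
    family: gamma
    sd: 368.0
    low: 2942.0
    high: 4414.0
  posthosp_mrs0:
    base: 3069.0
    family: gamma
    sd: 307.0
    low: 2455.0
    high: 3682.0
  posthosp_mrs1:
    base: 2966.0
    family: gamma
    sd: 297.0
    low: 2528.0
    high: 3791.0
  posthosp_mrs2:
    base: 3655.0
    family: gamma
    sd: 366.0
    low: 2925.0
    high: 4386.0
  posthosp_mrs3:
    base: 6277.0
    family: gamma
    sd: 628.0
    low: 5022.0
    high: 7532.0
  posthosp_mrs4:
    base: 12705.0
    family: gamma
    sd: 1271.0
    low: 10163.0
    high: 15246.0
  posthosp_mrs5:
    base: 18678.0
    family: gamma
    sd: 1868.0
    low: 14942.0
    high: 22413.0
  cost_recurrent:
    base: 22274.0
    family: gamma
    sd: 2227.0
    low: 21590.0
    high: 23034.0
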