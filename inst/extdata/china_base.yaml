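country: china
currency: CNY
start_age: 68.0
horizon_years: 20.0
cycle_length_years: 0.25
wtp: 85698.0
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
  acute_mrs0_1:
  - 1
  - 2
  acute_mrs2_5:
  - 3
  - 4
  - 5
  - 6
  acute_death: 7.0
posthosp:
  period: annual
  map:
    posthosp_mrs0_1:
    - 1
    - 2
    posthosp_mrs2_5:
    - 3
    - 4
    - 5
    - 6
life_table:
  age_start:
  - 68.0
  - 70.0
  - 75.0
  - 80.0
  - 85.0
  age_end:
  - 69.0
  - 74.0
  - 79.0
  - 84.0
  - 89.0
  annual_death_prob:
  - 0.01266
  - 0.02159
  - 0.03731
  - 0.0634
  - 0.1512
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
    base: 0.017
    family: beta
    sd: 0.001
    low: 0.015
    high: 0.02
  p_death_after_recurrence:
    base: 0.21
    family: beta
    sd: 0.011
    low: 0.189
    high: 0.232
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
    base: 0.95
    family: beta
    sd: 0.005
    low: 0.94
    high: 0.96
  u_mrs1:
    base: 0.89
    family: beta
    sd: 0.023
    low: 0.87
    high: 0.96
  u_mrs2:
    base: 0.67
    family: beta
    sd: 0.074
    low: 0.54
    high: 0.83
  u_mrs3:
    base: 0.44
    family: beta
    sd: 0.079
    low: 0.29
    high: 0.6
  u_mrs4:
    base: 0.16
    family: beta
    sd: 0.036
    low: 0.09
    high: 0.23
  u_mrs5:
    base: 0.1
    family: beta
    sd: 0.054
    low: 0.0
    high: 0.21
  u_recurrence:
    base: 0.42
    family: beta
    sd: 0.153
    low: 0.11
    high: 0.71
  du_sich:
    base: 0.38
    family: beta
    sd: 0.041
    low: 0.3
    high: 0.46
  discount_rate:
    base: 0.05
    family: fixed
    low: 0.0
    high: 0.08
  drug_price_per_mg:
    base: 37.200000000000003
    family: gamma
    sd: 3.72
    low: 36.240000000000002
    high: 48.840000000000003
  weight_kg:
    base: 75.0
    family: beta
    sd: 12.5
    low: 50.0
    high: 120.0
    scale_low: 50.0
    scale_high: 120.0
  infusion_first_hour:
    base: 15.6
    family: gamma
    sd: 1.56
    low: 5.0
    high: 30.0
  infusion_additional_hour:
    base: 1.0
    family: gamma
    sd: 0.1
    low: 0.5
    high: 2.0
  acute_mrs0_1:
    base: 12336.0
    family: gamma
    sd: 2102.0
    low: 7126.0
    high: 15533.0
  acute_mrs2_5:
    base: 16311.0
    family: gamma
    sd: 3106.0
    low: 8964.0
    high: 21389.0
  acute_death:
    base: 13979.0
    family: gamma
    sd: 2977.0
    low: 6568.0
    high: 18476.0
  cost_sich:
    base: 2979.0
    family: gamma
    sd: 1393.0
    low: 647.0
    high: 6217.0
  posthosp_mrs0_1:
    base: 8771.0
    family: gamma
    sd: 2140.0
    low: 2626.0
    high: 11188.0
  posthosp_mrs2_5:
    base: 13345.0
    family: gamma
    sd: 3356.0
    low: 3356.0
    high: 16783.0
  cost_recurrent:
    base: 18180.0
    family: gamma
    sd: 2272.0
    low: 13635.0
    high: 22726.0
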