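econ:
  annual_discount_rate: 0.05
  overhead_rate: 0.2
  exchange_rate: 2595.0
  thresholds_usd:
    gdp3: 3633.0
    gdp1: 1211.0
    opp_cost: 411.0
  psa_iterations: 1000
  psa_seed: 20260221
diag:
  fn_prob_pathology: 0.221
  fn_prob_liquid: 0.187
  nnt: 4
  pathology_unit_cost: 413933.0
  liquid_unit_cost_by_tier:
    samples_per_year:
    - 180.0
    - 300.0
    - 720.0
    - 900.0
    unit_cost:
    - 2161219.0
    - 1558645.0
    - 1437379.0
    - 1308450.0
  throughput_samples_per_year: 900.0
  availability: 1.0
  annual_incident_cases: 171
stages:
  p_limited_pathology: 0.396
  p_limited_liquid: 0.6
weights:
  active_disease:
    mean: 0.288
    se: 0.0526
  terminal_disease:
    mean: 0.54
    se: 0.0105
  post_treatment:
    mean: 0.049
    se: 0.0791
costs:
  chemo_drug:
    limited:
      mean: 2777813.0
      se: 361404.0
    advanced:
      mean: 2146124.0
      se: 300775.0
  chemo_nondrug:
    limited:
      mean: 1598578.0
      se: 96678.0
    advanced:
      mean: 1474471.0
      se: 82376.0
  followup_per_quarter:
    year1:
      mean: 87581.0
      se: 17516.0
    year2:
      mean: 23790.0
      se: 4758.0
    years3_5:
      mean: 11895.0
      se: 2379.0
  end_of_life:
    mean: 166380.0
    se: 41766.0
survival:
  beta0:
    mean: -2.702
    se: 0.4186
  beta_advanced:
    mean: 0.951
    se: 0.4101
  gamma:
    mean: 0.5
    se: 0.0781
  time_unit: months
life_table:
  age_start:
  - 0
  - 5
  - 10
  - 15
  - 20
  - 25
  - 30
  - 35
  - 40
  - 45
  - 50
  - 55
  - 60
  - 65
  - 70
  - 75
  - 80
  - 85
  - 90
  - 95
  q_annual:
  - 0.004594223559361
  - 0.000580322975919
  - 0.000483602479933
  - 0.000725403719899
  - 0.000967204959865
  - 0.001209006199832
  - 0.001450807439798
  - 0.002164350370212
  - 0.003228831336632
  - 0.004816850332506
  - 0.007185896290874
  - 0.010720097561414
  - 0.015992506303241
  - 0.023858015880359
  - 0.035591977327037
  - 0.053096990814362
  - 0.079211402267297
  - 0.118169526237152
  - 0.176288217749151
  - 0.262991117141345
  disability_weight:
  - 0.045
  - 0.05
  - 0.055
  - 0.075
  - 0.09
  - 0.095
  - 0.1
  - 0.105
  - 0.11
  - 0.12
  - 0.13
  - 0.145
  - 0.16
  - 0.18
  - 0.2
  - 0.22
  - 0.245
  - 0.27
  - 0.295
  - 0.32
run:
  cycle_length_months: 3.0
  post_cycle_length_months: 3.0
  disease_risk_horizon_months: 24.0
  treatment_duration_months: 3.0
  cohort_entry_age: 10.0
  max_age: 100.0
  fn_stage: advanced
  fn_recursive: yes
  background_yld_mode: all_alive
  yll_discount_form: continuous
  overhead_on_diagnosis: no
uncertainty:
  fn_prob_pathology:
    se: 0.045919211123219
    low: 0.13
    high: 0.31
  fn_prob_liquid:
    se: 0.035714941984726
    low: 0.08
    high: 0.22
  p_limited_pathology:
    se: 0.051021345692465
    low: 0.3
    high: 0.5
  p_limited_liquid:
    se: 0.102042691384931
    low: 0.4
    high: 0.8
  discount_rate:
    low: 0.035
    high: 0.1
  overhead_rate:
    low: 0.15
    high: 0.25
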