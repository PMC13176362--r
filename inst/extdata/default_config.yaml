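# Default cohort configuration: U.S. adults >= 45 y with type 2 diabetes
# and no stroke history, 2015-2018 baseline. All keys are optional; unset
# keys take the package defaults (see ?population_config).
"n": 1232
total_weight: 3.7e6
age_mean: 65.1
age_sd: 9.8
male_fraction: 0.558
target_proportions:
  glycemic: 0.576
  bp: 0.707
  statin: 0.600
  aspirin: 0.079
  smoking: 0.811
  weight: 0.108
  anticoagulant: 0.524
missingness_rates:
  hba1c: 0.05
  sbp: 0.03
  lipid_ratio: 0.08
  bmi: 0.02
adherence:
  glycemic: 0.5
  bp: 0.5
  statin: 0.3
  aspirin: 0.05
  smoking: 0.0
  weight: 0.0
  anticoagulant: 0.3
M: 10
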