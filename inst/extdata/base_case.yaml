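whtr_positivity: 0.226
whtr_stage1_sensitivity: 1.0
tests:
  ultrasound:
    se:
      mean: 0.52
      ci_low: 0.41
      ci_high: 0.64
      dist: beta
    sp:
      mean: 0.96
      ci_low: 0.91
      ci_high: 0.99
      dist: beta
  fibroscan:
    se:
      mean: 0.72
      ci_low: 0.64
      ci_high: 0.79
      dist: beta
    sp:
      mean: 0.98
      ci_low: 0.97
      ci_high: 0.98
      dist: beta
  mri_pdff:
    se:
      mean: 0.95
      ci_low: 0.92
      ci_high: 0.97
      dist: beta
    sp:
      mean: 0.92
      ci_low: 0.77
      ci_high: 0.98
      dist: beta
initial_stage_distribution:
  F0: 0.885
  F1: 0.052
  F2: 0.035
  F3: 0.016
  F4: 0.012
prevalence_by_age:
  '6': 0.05
  '7': 0.053939729289563
  '8': 0.05817087955073
  '9': 0.06271192963465
  '10': 0.067582035125981
  '11': 0.072800969150053
  '12': 0.078389045880674
  '13': 0.084367024744433
  '14': 0.090755993330109
costs:
  routine_exam: 2.9
  ultrasound: 16.5
  fibroscan: 13.0
  mri_pdff: 87.0
  blood_panel: 22.5
  program_fixed_annual: 10.5
  program_variable_annual: 21.699999999999999
utilities:
  F0:
    mean: 0.95
    ci_low: 0.93
    ci_high: 1.0
    dist: beta
  F1:
    mean: 0.85
    ci_low: 0.79
    ci_high: 0.92
    dist: beta
  F2:
    mean: 0.85
    ci_low: 0.79
    ci_high: 0.92
    dist: beta
  F3:
    mean: 0.73
    ci_low: 0.64
    ci_high: 0.82
    dist: beta
  F4:
    mean: 0.66
    ci_low: 0.49
    ci_high: 0.83
    dist: beta
  disease_free: 1.0
transitions:
  boys:
    F0_F1:
      mean: 0.004
      ci_low: 0.002
      ci_high: 0.006
      dist: beta
    F1_F2:
      mean: 0.033
      ci_low: 0.02
      ci_high: 0.051
      dist: beta
    F2_F3:
      mean: 0.033
      ci_low: 0.02
      ci_high: 0.051
      dist: beta
    F3_F4:
      mean: 0.034
      ci_low: 0.019
      ci_high: 0.064
      dist: beta
  girls:
    F0_F1:
      mean: 0.003
      ci_low: 0.002
      ci_high: 0.005
      dist: beta
    F1_F2:
      mean: 0.028
      ci_low: 0.016
      ci_high: 0.043
      dist: beta
    F2_F3:
      mean: 0.028
      ci_low: 0.016
      ci_high: 0.043
      dist: beta
    F3_F4:
      mean: 0.028
      ci_low: 0.016
      ci_high: 0.054
      dist: beta
  regression: 0.06
  regression_tx: 0.277
  response_rate: 0.4
  advanced_response_multiplier: 0.75
  adolescent_progression_factor: 1.25
  adolescent_regression_factor: 0.75
discount_rate: 0.03
horizon_years: 10
program_duration_years: ~
cohort_size: 100000
prop_boys: 0.5
wtp_thresholds:
  national: 30584.0
  beijing: 71415.5
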