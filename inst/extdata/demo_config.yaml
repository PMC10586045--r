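# Scaled-down demonstration configuration for the end-to-end runners.
# The longitudinal block encodes a two-group monthly fall-rate setting:
# a gradual pre-deployment rise, an immediate level drop in the first
# month of enterprise CDS deployment (month 29 of 34) and a small
# post-deployment trend change, with lag-1 autocorrelated noise.
seed: 20190601
multisite:
  sites: [A, B, C, D]
  n_stays: 3000
  alpha: 1
  smote:
    k: 5
    target_ratio: 1.0
  split:
    train_fraction: 0.7
longitudinal:
  site: A
  n_months: 34
  intervention_month: 29
  monthly_hospital_days: 20000
  lag: 1
  activity_n_stays: 300
  groups:
    control:
      baseline_level: 1.80
      baseline_slope: 0.02
      level_change: -0.50
      slope_change: -0.03
      noise_sd: 0.25
      ar1_coeff: 0.4
    experimental:
      baseline_level: 1.70
      baseline_slope: 0.01
      level_change: -0.12
      slope_change: -0.04
      noise_sd: 0.25
      ar1_coeff: 0.4
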