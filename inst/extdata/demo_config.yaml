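synth:
  n_ads: 8.0
  n_hc: 8.0
  n_trials: 40.0
  n_sensors: 16.0
  grid_dim:
  - 4.0
  - 4.0
  - 4.0
  grid_spacing: 20.0
  f0: 15.0
  harmonic_gains:
    '30': 0.4
    '45': 0.2
  a_mean_ads: 1.0
  a_mean_hc: 1.0
  a_sd: 0.2
  cv_ads: 0.25
  cv_hc: 0.4
  b_mean_ads: 0.25
  b_mean_hc: 0.45
  b_sd: 0.06
  ap_offset: -1.0
  ap_exponent: 1.0
  sensor_noise_sd: 0.1
  artifact_rate: 0.02
  artifact_gain: 10.0
  mmse_intercept: 18.0
  mmse_slope: 8.0
  mmse_sd: 2.0
  master_seed: 1.0
preprocess:
  k_amp: 3.0
  k_grad: 3.0
window_select:
  alpha: 0.001
  n_perm: 1000.0
  min_support: 0.8
beamform:
  band:
  - 14.5
  - 15.5
  window:
  - 200.0
  - 2000.0
  baseline_window:
  - -600.0
  - 0.0
  lambda_frac: 0.05
stats:
  outlier_k: 2.5
output:
  dir: ~
  write_subject_cache: no
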