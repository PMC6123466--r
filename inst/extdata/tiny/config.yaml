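n_samples: 12.0
purity_mean: 0.6
purity_sd: 0.12
depth_mean: 135.8
depth_dispersion: 8.0
error_rate: 0.001
germline_rate: 1.0
germline_pool_size: 200.0
germline_maf_log10_range:
- -5.0
- -0.69897
germline_beta_conc: 30.0
artifact_rate: 2.0
artifact_panel_prevalence: 0.05
artifact_tumor_prevalence: 0.1
artifact_vaf_range:
- 0.01
- 0.1
n1: 151.0
n2: 912.0
n3: 87.0
baseline_dist: exponential
baseline_hazard: 0.024
weibull_shape: 1.0
admin_censor_time: 25.0
censor_rate: 0.02
subtype_props:
- 0.5
- 0.42
- 0.04
- 0.02
- 0.02
per_study_n:
- 507.0
- 441.0
- 237.0
- 103.0
- 100.0
- 65.0
mpmb_correction: 1.6
qc_fail_rate: 0.02
seed: 424243
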