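# Demo run configuration for the synthetic soft-biometrics pipeline.
# Small cohort so `softgait run-all --config demo_config.yaml` finishes in
# well under a minute.
seed: 1
out_dir: softgait_demo_out
cohort:
  n_subjects: 10
  p_male: 0.5
  age_mean: 48.1
  age_sd: 12.7
  height_mean_male: 180
  height_mean_female: 169
  height_sd: 7
gait:
  sampling_rate: 128
  n_steps: 15
  n_sequences: 1
smooth_window: 9
feature_mode: combined
tasks:
  - gender
rf:
  n_trees: 200
  max_features_split: 7
validation:
  scheme: subject_wise
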