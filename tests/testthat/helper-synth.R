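# Shared fixture builders (everything is generated in code at test time).

make_step <- function(samples, sampling_rate = 128, subject_id = "S1",
                      sequence_id = "seq1") {
  n <- length(samples[[1]])
  rec <- imu_recording(samples, sampling_rate, subject_id = subject_id,
                       sequence_id = sequence_id)
  step_segment(rec, 1L, n + 1L)
}

# A random 6-channel step segment of length n.
random_step <- function(n, seed) {
  set.seed(seed)
  samples <- stats::setNames(
    lapply(imu_channels(), function(ch) stats::rnorm(n)), imu_channels())
  make_step(samples)
}

# Cohort + per-step feature table for classification tests.
cohort_features <- function(n_subjects, n_steps, cfg, seed,
                            demographics = gait_demographics()) {
  cohort <- generate_cohort(n_subjects, demographics, seed = seed)
  features <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    synth <- generate_recording(cohort[i, ], n_steps, cfg)
    steps <- segment_recording(synth$recording)
    extract_feature_table(steps)
  }))
  list(cohort = cohort, features = features)
}

null_gait_config <- function(seed)
  gait_config(height_cadence_coeff = 0, sex_amplitude_delta = 0,
              age_variability_coeff = 0, subject_random_effect_sd = 0,
              seed = seed)
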