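# Declarative run configuration (YAML). Unknown keys are rejected so typos
# fail loudly rather than silently falling back to defaults.

run_config_schema <- function() list(
  seed = NULL, out_dir = NULL,
  cohort = c("n_subjects", "p_male", "age_mean", "age_sd",
             "height_mean_male", "height_mean_female", "height_sd"),
  gait = c("sampling_rate", "base_step_duration", "height_cadence_coeff",
           "reference_height", "sex_amplitude_delta", "age_variability_coeff",
           "subject_random_effect_sd", "noise_sd", "baseline_x_accel",
           "n_steps", "n_sequences"),
  smooth_window = NULL,
  segmentation = c("delta_d", "delta_h", "mode"),
  feature_mode = NULL,
  tasks = NULL,
  rf = c("n_trees", "max_features_split"),
  validation = c("scheme", "k"))

#' Read a run configuration file
#'
#' Parses a YAML run configuration and validates it against the known schema;
#' unknown top-level or nested keys are rejected. See the packaged demo
#' config (`system.file("extdata", "demo_config.yaml", package =
#' "softgait")`) for the full key set.
#'
#' @param path YAML file path.
#' @return Named list of configuration values plus an attribute
#'   `config_hash` (MD5 of the file) for provenance.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  schema <- run_config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(cfg)) {
    allowed <- schema[[k]]
    if (!is.null(allowed) && is.list(cfg[[k]])) {
      bad <- setdiff(names(cfg[[k]]), allowed)
      if (length(bad) > 0L)
        stop("unknown key(s) under '", k, "': ", paste(bad, collapse = ", "))
    }
  }
  attr(cfg, "config_hash") <- unname(tools::md5sum(path))
  cfg
}

# Resolve a run config (with defaults) into the objects the pipeline needs.
resolve_run_config <- function(cfg, seed_override = NULL) {
  g <- function(x, key, default) if (!is.null(x[[key]])) x[[key]] else default
  seed <- if (!is.null(seed_override)) as.integer(seed_override)
          else as.integer(g(cfg, "seed", 1L))
  co <- cfg$cohort
  demo <- gait_demographics(
    p_male = g(co, "p_male", 12 / 26),
    age_mean = g(co, "age_mean", 48.1), age_sd = g(co, "age_sd", 12.7),
    height_mean_male = g(co, "height_mean_male", 180),
    height_mean_female = g(co, "height_mean_female", 169),
    height_sd = g(co, "height_sd", 7))
  ga <- cfg$gait
  gcfg <- gait_config(
    sampling_rate = g(ga, "sampling_rate", 128),
    base_step_duration = g(ga, "base_step_duration", 0.55),
    height_cadence_coeff = g(ga, "height_cadence_coeff", 0.002),
    reference_height = g(ga, "reference_height", 174),
    sex_amplitude_delta = g(ga, "sex_amplitude_delta", 0.25),
    age_variability_coeff = g(ga, "age_variability_coeff", 4e-4),
    subject_random_effect_sd = g(ga, "subject_random_effect_sd", 0.08),
    noise_sd = g(ga, "noise_sd", 0.05),
    baseline_x_accel = g(ga, "baseline_x_accel", 9.81),
    seed = seed)
  se <- cfg$segmentation
  seg <- if (!is.null(se) && !is.null(se$delta_d) && !is.null(se$delta_h))
    segmentation_config(se$delta_d, se$delta_h, g(se, "mode", "prominence"))
  else NULL
  va <- cfg$validation
  list(
    seed = seed,
    out_dir = g(cfg, "out_dir", "."),
    n_subjects = g(co, "n_subjects", 26L),
    n_steps = g(ga, "n_steps", 20L),
    n_sequences = g(ga, "n_sequences", 1L),
    demographics = demo, gait = gcfg, segmentation = seg,
    smooth_window = g(cfg, "smooth_window", 9L),
    feature_mode = g(cfg, "feature_mode", "combined"),
    tasks = g(cfg, "tasks", c("gender", "age_group", "height_group")),
    rf = rf_config(n_trees = g(cfg$rf, "n_trees", 400L),
                   max_features_split = g(cfg$rf, "max_features_split", 7L),
                   seed = seed),
    plan = validation_plan(scheme = g(va, "scheme", "subject_wise"),
                           k = g(va, "k", 10L), seed = seed),
    config_hash = if (is.null(attr(cfg, "config_hash"))) NA_character_
                  else attr(cfg, "config_hash"))
}
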