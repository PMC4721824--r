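# Demographically conditioned synthetic walking-IMU generator.
#
# The signal family is a per-step sum of sinusoidal harmonics of the step
# frequency on each of the six channels: the simplest family producing the
# one-peak-one-valley-per-step structure that valley-based step segmentation
# relies on. Attribute couplings (cadence <-> height, amplitude <-> sex,
# step-to-step variability <-> age) and per-subject idiosyncratic
# amplitude/phase effects are modelling choices, not biomechanics; all
# coefficients live in the config so effects can be dialled to zero.

# -- deterministic seed plumbing ---------------------------------------------

str_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(as.character(s))) h <- (h * 31 + c) %% 2147483647
  h
}

combine_seeds <- function(...) {
  vals <- c(...)
  h <- 0
  for (v in vals) h <- (h * 48271 + (as.numeric(v) %% 2147483647)) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# -- configuration -----------------------------------------------------------

default_harmonics <- function() {
  chans <- imu_channels()
  h1 <- list(
    order = 1L,
    amplitude = stats::setNames(c(1.5, 0.5, 0.8, 25, 40, 30), chans),
    phase     = stats::setNames(c(pi, 0, pi / 2, 0, pi / 3, pi / 2), chans))
  h2 <- list(
    order = 2L,
    amplitude = stats::setNames(c(0.3, 0.15, 0.25, 8, 12, 10), chans),
    phase     = stats::setNames(c(pi, pi / 4, 0, pi / 2, 0, pi / 4), chans))
  list(h1, h2)
}

#' Gait signal model configuration
#'
#' Parameters of the synthetic walking-signal generator. Step duration for a
#' subject is `base_step_duration + height_cadence_coeff * (height -
#' reference_height)` plus zero-mean Gaussian step-to-step jitter with
#' standard deviation `age_variability_coeff * age` (seconds). Males have the
#' harmonic amplitudes of the channels in `sex_amplitude_channels` scaled by
#' `1 + sex_amplitude_delta`. Each subject carries idiosyncratic per-channel
#' log-amplitude and phase offsets with standard deviation
#' `subject_random_effect_sd`, drawn deterministically from `(seed,
#' subject_id)`. The cranio-caudal acceleration channel (Ax) has a positive
#' baseline (`baseline_x_accel`, emulating gravity) and, under the default
#' harmonics, exactly one valley (at the step boundary) and one peak per step.
#'
#' @param sampling_rate Hz.
#' @param base_step_duration seconds, step duration at the reference height.
#' @param height_cadence_coeff seconds of extra step duration per cm of height.
#' @param reference_height cm; cadence centring constant (cohort-mean scale).
#' @param sex_amplitude_delta fractional amplitude increase for males on
#'   `sex_amplitude_channels`.
#' @param sex_amplitude_channels channels carrying the sex effect.
#' @param age_variability_coeff seconds of step-duration jitter SD per year.
#' @param subject_random_effect_sd SD of per-subject log-amplitude and phase
#'   (radian) offsets.
#' @param noise_sd additive white-noise SD, channel units.
#' @param baseline_x_accel constant offset on Ax, m/s^2.
#' @param harmonics list of harmonics, each `list(order, amplitude, phase)`
#'   with named per-channel amplitude/phase vectors. At least one harmonic
#'   must have nonzero Ax amplitude.
#' @param seed integer master seed for all randomness derived from this config.
#' @return An object of class `gait_config`.
#' @export
gait_config <- function(sampling_rate = 128,
                        base_step_duration = 0.55,
                        height_cadence_coeff = 0.002,
                        reference_height = 174,
                        sex_amplitude_delta = 0.25,
                        sex_amplitude_channels = c("Ax", "Gy"),
                        age_variability_coeff = 4e-4,
                        subject_random_effect_sd = 0.08,
                        noise_sd = 0.05,
                        baseline_x_accel = 9.81,
                        harmonics = default_harmonics(),
                        seed = 1L) {
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  ax_amp <- vapply(harmonics, function(h) abs(h$amplitude[["Ax"]]), numeric(1))
  if (!any(ax_amp > 0))
    stop("at least one harmonic must have nonzero amplitude on Ax")
  if (!all(sex_amplitude_channels %in% imu_channels()))
    stop("unknown channel in sex_amplitude_channels")
  structure(list(
    sampling_rate = sampling_rate,
    base_step_duration = base_step_duration,
    height_cadence_coeff = height_cadence_coeff,
    reference_height = reference_height,
    sex_amplitude_delta = sex_amplitude_delta,
    sex_amplitude_channels = sex_amplitude_channels,
    age_variability_coeff = age_variability_coeff,
    subject_random_effect_sd = subject_random_effect_sd,
    noise_sd = noise_sd,
    baseline_x_accel = baseline_x_accel,
    harmonics = harmonics,
    seed = as.integer(seed)
  ), class = "gait_config")
}

#' Cohort demographic distributions
#'
#' Defaults emulate a mixed adult cohort: 12:14 male-to-female ratio, age
#' 48.1 +/- 12.7 years, and sex-conditional heights whose mixture mean is
#' about 174 cm.
#'
#' @param p_male proportion of male subjects (sex counts are exact:
#'   `round(n * p_male)` males).
#' @param age_mean,age_sd normal age distribution (years), truncated to > 0.
#' @param height_mean_male,height_mean_female,height_sd sex-conditional
#'   normal height distributions (cm), truncated to > 0.
#' @return A list of class `gait_demographics`.
#' @export
gait_demographics <- function(p_male = 12 / 26,
                              age_mean = 48.1, age_sd = 12.7,
                              height_mean_male = 180,
                              height_mean_female = 169,
                              height_sd = 7) {
  stopifnot(p_male >= 0, p_male <= 1, age_sd >= 0, height_sd >= 0,
            age_mean > 0, height_mean_male > 0, height_mean_female > 0)
  structure(list(p_male = p_male, age_mean = age_mean, age_sd = age_sd,
                 height_mean_male = height_mean_male,
                 height_mean_female = height_mean_female,
                 height_sd = height_sd),
            class = "gait_demographics")
}

# -- cohort generation -------------------------------------------------------

rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Generate a synthetic cohort's subject metadata
#'
#' Draws `n_subjects` subjects with sex, age (years) and height (cm) from the
#' demographic distributions. The male count is exact
#' (`round(n_subjects * p_male)`); ages and heights are truncated-normal
#' draws. Deterministic given `seed`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param demographics a [gait_demographics()] object.
#' @param seed integer seed.
#' @return A `data.frame` with columns `subject_id`, `sex` (`"female"` /
#'   `"male"`), `age`, `height`.
#' @export
generate_cohort <- function(n_subjects, demographics = gait_demographics(),
                            seed = 1L) {
  stopifnot(inherits(demographics, "gait_demographics"))
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  d <- demographics
  sex_degenerate <- d$p_male <= 0 || d$p_male >= 1
  age_degenerate <- d$age_sd == 0
  height_degenerate <- d$height_sd == 0 &&
    (sex_degenerate || d$height_mean_male == d$height_mean_female)
  if (sex_degenerate && age_degenerate && height_degenerate)
    stop("degenerate demographics: sex, age and height are all single-valued; ",
         "no classification task would be learnable")
  n_male <- round(n_subjects * d$p_male)
  if (n_male == 0 || n_male == n_subjects)
    stop("demographics must cover both sexes at this cohort size")
  with_seed(combine_seeds(seed, 101L), {
    sex <- sample(rep(c("male", "female"), c(n_male, n_subjects - n_male)))
    age <- rnorm_pos(n_subjects, d$age_mean, d$age_sd)
    height <- ifelse(sex == "male",
                     rnorm_pos(n_subjects, d$height_mean_male, d$height_sd),
                     rnorm_pos(n_subjects, d$height_mean_female, d$height_sd))
    data.frame(
      subject_id = sprintf("S%02d", seq_len(n_subjects)),
      sex = sex, age = age, height = height,
      stringsAsFactors = FALSE)
  })
}

# -- recording generation ----------------------------------------------------

subject_effects <- function(subject_id, cfg) {
  with_seed(combine_seeds(cfg$seed, str_hash(subject_id), 7L), {
    list(
      amp = exp(stats::rnorm(6, 0, cfg$subject_random_effect_sd)),
      phase = stats::rnorm(6, 0, cfg$subject_random_effect_sd))
  })
}

#' Generate one synthetic walking recording with ground-truth step boundaries
#'
#' Builds an `n_steps`-step 6-channel walking signal for one subject. Within
#' step `k` of duration `T_k`, each channel is the sum over configured
#' harmonics of `A * cos(2*pi*order*phi + phase)` with `phi` the within-step
#' phase in `[0, 1)`, scaled by the subject's idiosyncratic amplitude effect
#' and (for males, on the designated channels) by `1 + sex_amplitude_delta`;
#' Ax additionally carries the positive gravity baseline so its valleys (at
#' the step boundaries) are well defined. White Gaussian noise of SD
#' `noise_sd` is added to every channel. Bit-identical output for identical
#' `(subject, n_steps, cfg, sequence_id)`.
#'
#' @param subject one row of a [generate_cohort()] data frame (or any list
#'   with `subject_id`, `sex`, `age`, `height`).
#' @param n_steps number of steps (>= 1).
#' @param cfg a [gait_config()].
#' @param sequence_id sequence label; different sequences of the same subject
#'   share the subject's idiosyncratic effects but have independent jitter
#'   and noise.
#' @param sensor_location carried into the recording metadata.
#' @return A list of class `synthetic_recording` with elements `recording`
#'   (an [imu_recording()]) and `true_step_boundaries` (1-based first frame
#'   of each step, strictly increasing, length `n_steps`).
#' @export
generate_recording <- function(subject, n_steps, cfg = gait_config(),
                               sequence_id = "seq1",
                               sensor_location = "lower_back") {
  stopifnot(inherits(cfg, "gait_config"))
  if (n_steps < 1) stop("n_steps must be >= 1")
  subject <- as.list(subject)
  fs <- cfg$sampling_rate
  base_dur <- cfg$base_step_duration +
    cfg$height_cadence_coeff * (subject$height - cfg$reference_height)
  jitter_sd <- cfg$age_variability_coeff * subject$age

  seq_seed <- combine_seeds(cfg$seed, str_hash(subject$subject_id),
                            str_hash(sequence_id), 13L)
  eff <- subject_effects(subject$subject_id, cfg)

  with_seed(seq_seed, {
    durations <- base_dur + stats::rnorm(n_steps, 0, jitter_sd)
    if (any(durations <= 2 / fs))
      stop("modulated step duration <= 2/sampling_rate: unresolvable step")
    starts <- cumsum(c(0, durations))          # seconds; length n_steps + 1
    total <- starts[n_steps + 1]
    n_frames <- floor(total * fs)
    t <- (seq_len(n_frames) - 1) / fs
    step_of <- findInterval(t, starts, rightmost.closed = FALSE)
    step_of[step_of > n_steps] <- n_steps
    phi <- (t - starts[step_of]) / durations[step_of]

    sex_mult <- stats::setNames(rep(1, 6), imu_channels())
    if (identical(subject$sex, "male"))
      sex_mult[cfg$sex_amplitude_channels] <- 1 + cfg$sex_amplitude_delta

    channels <- stats::setNames(vector("list", 6), imu_channels())
    for (ci in seq_along(imu_channels())) {
      ch <- imu_channels()[ci]
      sig <- numeric(n_frames)
      for (h in cfg$harmonics) {
        a <- h$amplitude[[ch]] * eff$amp[ci] * sex_mult[[ch]]
        if (a != 0)
          sig <- sig + a * cos(2 * pi * h$order * phi +
                                 h$phase[[ch]] + eff$phase[ci])
      }
      if (ch == "Ax") sig <- sig + cfg$baseline_x_accel
      if (cfg$noise_sd > 0) sig <- sig + stats::rnorm(n_frames, 0, cfg$noise_sd)
      channels[[ch]] <- sig
    }

    boundaries <- floor(starts[seq_len(n_steps)] * fs) + 1L
    rec <- imu_recording(channels, fs,
                         subject_id = subject$subject_id,
                         sequence_id = sequence_id,
                         sensor_location = sensor_location)
    structure(list(recording = rec,
                   true_step_boundaries = as.integer(boundaries),
                   step_durations = durations),
              class = "synthetic_recording")
  })
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("<synthetic_recording> %d true steps\n",
              length(x$true_step_boundaries)))
  print(x$recording)
  invisible(x)
}
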