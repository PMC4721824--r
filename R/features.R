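# Per-step feature extraction: 2 step-level temporal features plus 8
# statistics on each of the 6 channels = 50 features per step.

#' Names of the per-step features
#'
#' Two step-level temporal features (`step_length` in frames and
#' `step_duration` in seconds, computed once from the Ax segmentation since
#' the cut is identical in every axis) plus, for each channel, mean, standard
#' deviation, minimum, maximum, root mean square, entropy (bits), signal
#' energy and spectral amplitude. Selector modes: `"combined"` all 50
#' features; `"accel_only"` and `"gyro_only"` each 26 (the two temporal
#' features are channel-independent and belong to every set).
#'
#' @param mode `"combined"`, `"accel_only"` or `"gyro_only"`.
#' @return Character vector of feature (column) names, in contract order.
#' @export
feature_names <- function(mode = c("combined", "accel_only", "gyro_only")) {
  mode <- match.arg(mode)
  chans <- switch(mode,
    combined = imu_channels(),
    accel_only = c("Ax", "Ay", "Az"),
    gyro_only = c("Gx", "Gy", "Gz"))
  stats <- c("mean", "sd", "min", "max", "rms", "entropy", "energy",
             "amplitude")
  c("step_length", "step_duration",
    as.vector(t(outer(chans, stats, paste, sep = "_"))))
}

#' Entropy of a sample vector (bits)
#'
#' Normalised-magnitude entropy `-sum(p_i * log2(p_i))` with weights
#' `p_i = m_i / sum(m_i)` where `m_i = |s_i| / max |s_i|`. Magnitudes are
#' used because the weights must form a probability distribution on signed
#' channels; zero weights contribute zero. The result lies in
#' `[0, log2(N)]` and is invariant under positive rescaling of the samples.
#' An all-zero vector yields 0 with a warning.
#'
#' @param samples numeric vector.
#' @return Entropy in bits.
#' @export
channel_entropy <- function(samples) {
  m <- abs(samples)
  mx <- max(m)
  if (mx == 0) {
    warning("all-zero samples: entropy defined as 0")
    return(0)
  }
  p <- (m / mx) / sum(m / mx)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Signal energy of a sample vector
#'
#' Sum of squared sample magnitudes, `sum(|x[n]|^2)`; equals `N * rms^2`.
#'
#' @param samples numeric vector.
#' @return Energy in squared channel units.
#' @export
channel_energy <- function(samples) sum(samples^2)

#' Maximum amplitude of the frequency spectrum
#'
#' Largest magnitude over the bins of the unnormalised discrete Fourier
#' transform of the step's samples, excluding the zero-frequency (DC) bin:
#' the mean is already a separate feature, and on the gravity-offset
#' acceleration channel a DC term would otherwise dominate every amplitude.
#' For a pure cosine of amplitude `a` at an exact bin frequency the value is
#' `N/2 * a` (`N * a` at the Nyquist bin).
#'
#' @param samples numeric vector, length >= 2.
#' @param sampling_rate Hz (present for interface completeness; the maximum
#'   magnitude does not depend on it).
#' @return Spectral amplitude in channel units.
#' @export
channel_amplitude <- function(samples, sampling_rate = NULL) {
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples for a spectrum")
  max(Mod(stats::fft(samples))[-1L])
}

#' Extract the per-step feature vector
#'
#' Computes the full feature set for one step: `step_length = N` frames,
#' `step_duration = N / sampling_rate` seconds, and per channel the mean,
#' sample standard deviation (N-1 denominator), global minimum and maximum,
#' root mean square, [channel_entropy()], [channel_energy()] and
#' [channel_amplitude()].
#'
#' @param step a [step_segment()] with at least 2 frames.
#' @param step_index optional integer identifying the step within its
#'   sequence.
#' @return A one-row `data.frame`: identity columns (`subject_id`,
#'   `sequence_id`, `sensor_location`, `step_index`) followed by the 50
#'   feature columns of [feature_names()].
#' @export
extract_features <- function(step, step_index = NA_integer_) {
  stopifnot(inherits(step, "step_segment"))
  n <- step$end_frame - step$start_frame
  if (n < 2L) stop("step must have at least 2 frames (sd undefined)")
  out <- list(
    subject_id = step$subject_id,
    sequence_id = step$sequence_id,
    sensor_location = step$sensor_location,
    step_index = as.integer(step_index),
    step_length = as.numeric(n),
    step_duration = n / step$sampling_rate)
  for (ch in imu_channels()) {
    s <- step$samples[[ch]]
    out[[paste0(ch, "_mean")]] <- mean(s)
    out[[paste0(ch, "_sd")]] <- stats::sd(s)
    out[[paste0(ch, "_min")]] <- min(s)
    out[[paste0(ch, "_max")]] <- max(s)
    out[[paste0(ch, "_rms")]] <- sqrt(mean(s^2))
    out[[paste0(ch, "_entropy")]] <- suppressWarnings(channel_entropy(s))
    out[[paste0(ch, "_energy")]] <- channel_energy(s)
    out[[paste0(ch, "_amplitude")]] <- channel_amplitude(s, step$sampling_rate)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Extract a feature table from a list of step segments
#'
#' @param steps list of [step_segment()] objects (e.g. from
#'   [segment_recording()]).
#' @return A `data.frame` with one row per step; `step_index` numbers the
#'   steps within the supplied list.
#' @export
extract_feature_table <- function(steps) {
  if (length(steps) == 0L)
    stop("no steps to extract features from")
  do.call(rbind, lapply(seq_along(steps), function(i)
    extract_features(steps[[i]], step_index = i)))
}

#' Select identity plus feature columns for a mode
#'
#' @param features a feature table from [extract_feature_table()].
#' @param mode a [feature_names()] mode.
#' @return The feature table restricted to identity columns and the selected
#'   feature set.
#' @export
select_features <- function(features,
                            mode = c("combined", "accel_only", "gyro_only")) {
  mode <- match.arg(mode)
  id_cols <- intersect(c("subject_id", "sequence_id", "sensor_location",
                         "step_index", "label"), names(features))
  features[, c(id_cols, feature_names(mode)), drop = FALSE]
}
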