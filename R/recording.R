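#' @keywords internal
"_PACKAGE"

#' Channel names of a 6-channel IMU recording
#'
#' Three acceleration axes (m/s^2) followed by three angular-velocity axes
#' (deg/s). Axis semantics: x = cranio-caudal (head-to-foot), y = transverse,
#' z = anteroposterior.
#'
#' @return Character vector `c("Ax","Ay","Az","Gx","Gy","Gz")`.
#' @export
imu_channels <- function() c("Ax", "Ay", "Az", "Gx", "Gy", "Gz")

#' Construct an IMU recording
#'
#' Container for one sensor's 6-channel inertial time series plus identity
#' metadata. All channels must have equal length.
#'
#' @param channels named list of six equal-length numeric vectors
#'   (`Ax`,`Ay`,`Az` in m/s^2; `Gx`,`Gy`,`Gz` in deg/s).
#' @param sampling_rate sampling frequency in Hz (> 0).
#' @param subject_id,sequence_id opaque identity strings.
#' @param sensor_location one of `"chest"`, `"lower_back"`, `"right_wrist"`,
#'   `"left_ankle"`, `"other"`.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(channels, sampling_rate,
                          subject_id = "S1", sequence_id = "seq1",
                          sensor_location = "lower_back") {
  stopifnot(is.list(channels))
  if (!identical(sort(names(channels)), sort(imu_channels())))
    stop("channels must be named ", paste(imu_channels(), collapse = ", "))
  channels <- channels[imu_channels()]
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all 6 channels must have equal length")
  if (!all(vapply(channels, function(v) all(is.finite(v)), logical(1))))
    stop("channels must contain only finite values")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  sensor_location <- match.arg(sensor_location,
    c("chest", "lower_back", "right_wrist", "left_ankle", "other"))
  structure(list(
    subject_id = as.character(subject_id),
    sequence_id = as.character(sequence_id),
    sensor_location = sensor_location,
    sampling_rate = sampling_rate,
    channels = lapply(channels, as.numeric),
    n_frames = unname(lens[1])
  ), class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> subject=%s sequence=%s location=%s\n",
              x$subject_id, x$sequence_id, x$sensor_location))
  cat(sprintf("  %d frames @ %g Hz (%.2f s), channels: %s\n",
              x$n_frames, x$sampling_rate, x$n_frames / x$sampling_rate,
              paste(imu_channels(), collapse = " ")))
  invisible(x)
}

#' Construct a single-step segment
#'
#' One step's span and per-channel samples, cut from an [imu_recording()].
#' Frame spans are half-open `[start_frame, end_frame)` in 1-based frame
#' indices, so the segment length is `end_frame - start_frame`.
#'
#' @param recording the parent `imu_recording`.
#' @param start_frame,end_frame 1-based frame indices, `end_frame > start_frame`.
#' @return An object of class `step_segment` carrying the six sample vectors,
#'   identity metadata and the sampling rate.
#' @export
step_segment <- function(recording, start_frame, end_frame) {
  stopifnot(inherits(recording, "imu_recording"))
  start_frame <- as.integer(start_frame); end_frame <- as.integer(end_frame)
  if (end_frame <= start_frame) stop("end_frame must exceed start_frame")
  if (start_frame < 1L || end_frame > recording$n_frames + 1L)
    stop("segment span outside recording")
  idx <- start_frame:(end_frame - 1L)
  structure(list(
    subject_id = recording$subject_id,
    sequence_id = recording$sequence_id,
    sensor_location = recording$sensor_location,
    sampling_rate = recording$sampling_rate,
    start_frame = start_frame,
    end_frame = end_frame,
    samples = lapply(recording$channels, function(v) v[idx])
  ), class = "step_segment")
}

#' @export
print.step_segment <- function(x, ...) {
  cat(sprintf("<step_segment> subject=%s sequence=%s frames [%d, %d) (N=%d)\n",
              x$subject_id, x$sequence_id, x$start_frame, x$end_frame,
              x$end_frame - x$start_frame))
  invisible(x)
}
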