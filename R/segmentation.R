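# Step decomposition by peak/valley detection on the cranio-caudal
# acceleration axis. Valleys cut all six channels at identical frames so the
# step length is consistent across axes.

#' Segmentation thresholds
#'
#' `delta_d` is the minimum distance (frames) between two retained extrema of
#' the same kind; `delta_h` is the minimum height of an extremum. By default
#' `delta_h` is interpreted as topographic prominence (height of a peak above
#' the higher of its two surrounding saddles): absolute height is meaningless
#' on signed gyro channels or a baseline-shifted acceleration, while
#' prominence captures "minimum height of the peak" robustly. Set
#' `mode = "height"` for the absolute-value interpretation.
#'
#' @param delta_d minimum frame distance between extrema (>= 1).
#' @param delta_h minimum prominence (or height), channel units (>= 0).
#' @param mode `"prominence"` (default) or `"height"`.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(delta_d, delta_h,
                                mode = c("prominence", "height")) {
  mode <- match.arg(mode)
  delta_d <- as.integer(delta_d)
  if (delta_d < 1L) stop("delta_d must be >= 1")
  if (delta_h < 0) stop("delta_h must be >= 0")
  structure(list(delta_d = delta_d, delta_h = delta_h, mode = mode),
            class = "segmentation_config")
}

#' Default segmentation thresholds for a recording
#'
#' Heuristic defaults: `delta_d = 0.4 s * sampling_rate` and `delta_h = 0.5 *
#' (90th - 10th percentile of the Ax channel)`. These stand in for
#' thresholds that would be chosen by experimentation on real data.
#'
#' @param recording an [imu_recording()] (typically already smoothed).
#' @return A [segmentation_config()].
#' @export
default_segmentation_config <- function(recording) {
  stopifnot(inherits(recording, "imu_recording"))
  q <- stats::quantile(recording$channels$Ax, c(0.1, 0.9), names = FALSE)
  segmentation_config(delta_d = max(1L, round(0.4 * recording$sampling_rate)),
                      delta_h = 0.5 * (q[2] - q[1]))
}

# Topographic prominence of a strict local maximum at index i: height above
# the higher of the minima separating it from the nearest higher samples (or
# the signal edges).
peak_prominence <- function(x, i) {
  n <- length(x)
  left_min <- x[i]
  j <- i - 1L
  while (j >= 1L && x[j] <= x[i]) {
    if (x[j] < left_min) left_min <- x[j]
    j <- j - 1L
  }
  right_min <- x[i]
  j <- i + 1L
  while (j <= n && x[j] <= x[i]) {
    if (x[j] < right_min) right_min <- x[j]
    j <- j + 1L
  }
  x[i] - max(left_min, right_min)
}

# Strict local maxima of x filtered by delta_h (prominence or height) and
# delta_d: conflicting candidates are resolved greedily by descending
# prominence (ties to the earlier index).
find_peaks <- function(x, delta_d, delta_h, mode = "prominence") {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
  if (length(cand) == 0L) return(integer(0))
  prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
  keep <- if (mode == "prominence") prom >= delta_h else x[cand] >= delta_h
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) == 0L) return(integer(0))
  ord <- order(-prom, cand)
  kept <- integer(0)
  for (k in ord) {
    if (all(abs(cand[k] - kept) >= delta_d)) kept <- c(kept, cand[k])
  }
  sort(kept)
}

#' Detect peaks and valleys in one channel
#'
#' Peaks are strict local maxima with prominence (or height, per `mode`) at
#' least `delta_h`, thinned so that retained peaks are at least `delta_d`
#' frames apart (the more prominent of two conflicting candidates wins, ties
#' to the earlier index). Valleys are detected as peaks of the negated
#' signal under the same thresholds.
#'
#' @param x numeric vector (length >= 3 for any extrema to exist).
#' @param cfg a [segmentation_config()].
#' @return List with integer vectors `peaks` and `valleys` (1-based indices).
#' @export
detect_extrema <- function(x, cfg) {
  stopifnot(inherits(cfg, "segmentation_config"))
  list(peaks = find_peaks(x, cfg$delta_d, cfg$delta_h, cfg$mode),
       valleys = find_peaks(-x, cfg$delta_d, cfg$delta_h, cfg$mode))
}

#' Cut a recording into single steps at valley indices
#'
#' The k-th of `length(valleys) - 1` segments spans the half-open frame
#' interval `[valleys[k], valleys[k+1])`; all six channels are cut at
#' identical indices, so segments tile the signal between the first and last
#' valley with no gaps or overlaps.
#'
#' @param recording an [imu_recording()].
#' @param valleys strictly increasing 1-based frame indices.
#' @return List of [step_segment()] objects (empty, with a warning, when
#'   fewer than 2 valleys are supplied).
#' @export
cut_steps <- function(recording, valleys) {
  stopifnot(inherits(recording, "imu_recording"))
  if (length(valleys) >= 2L && any(diff(valleys) <= 0))
    stop("valleys must be strictly increasing")
  if (length(valleys) < 2L) {
    warning("fewer than 2 valleys: sequence yields no steps")
    return(list())
  }
  lapply(seq_len(length(valleys) - 1L), function(k)
    step_segment(recording, valleys[k], valleys[k + 1L]))
}

#' Smooth and segment a recording into steps
#'
#' Convenience pipeline stage: smooths the recording by moving average,
#' detects valleys on the cranio-caudal acceleration channel (Ax), and cuts
#' all channels of the *smoothed* recording at those valleys.
#'
#' @param recording an [imu_recording()] of raw signals.
#' @param cfg a [segmentation_config()], or `NULL` for
#'   [default_segmentation_config()] computed on the smoothed recording.
#' @param smooth_window moving-average window (frames, odd); 0 or 1 disables
#'   smoothing.
#' @return List of [step_segment()] objects.
#' @export
segment_recording <- function(recording, cfg = NULL, smooth_window = 9L) {
  stopifnot(inherits(recording, "imu_recording"))
  rec <- if (smooth_window > 1L) moving_average(recording, smooth_window)
         else recording
  if (is.null(cfg)) cfg <- default_segmentation_config(rec)
  ext <- detect_extrema(rec$channels$Ax, cfg)
  cut_steps(rec, ext$valleys)
}
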