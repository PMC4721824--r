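# Moving-average smoothing of raw 6-channel signals.

#' Centred moving average of one signal
#'
#' Width-`window` centred moving average; at the edges the window shrinks to
#' the available samples, so no values are fabricated and the output length
#' equals the input length. A centred (rather than trailing) window is used
#' so smoothing introduces no phase lag that would shift valley positions,
#' which feed step boundaries downstream.
#'
#' @param x numeric vector.
#' @param window odd integer >= 1.
#' @return Numeric vector of the same length as `x`.
#' @export
moving_average_vec <- function(x, window = 9L) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window %% 2L == 0L) stop("window must be odd (centred average)")
  n <- length(x)
  if (n == 0L) return(x)
  h <- window %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth an IMU recording by moving average
#'
#' Applies [moving_average_vec()] to each of the six channels; metadata and
#' length are unchanged.
#'
#' @param recording an [imu_recording()].
#' @param window odd window width in frames (default 9).
#' @return The smoothed `imu_recording`.
#' @export
moving_average <- function(recording, window = 9L) {
  stopifnot(inherits(recording, "imu_recording"))
  out <- recording
  out$channels <- lapply(recording$channels, moving_average_vec,
                         window = window)
  out
}
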