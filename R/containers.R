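#' Spike train container
#'
#' An ordered set of spike times with the duration of the recording window.
#' All burst statistics are computed from this container.
#'
#' @param times numeric vector of spike times in seconds, strictly increasing,
#'   all in `[0, duration)`.
#' @param duration recording duration in seconds (> 0).
#' @param source_id optional label identifying the recording.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times, duration, source_id = NA_character_) {
  stop_if_not_scalar_pos(duration, "duration")
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times must not contain NA")
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  if (length(times) && (times[1] < 0 || times[length(times)] >= duration))
    stop("spike times must lie in [0, duration)")
  structure(list(times = times, duration = duration, source_id = source_id),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.6g s (%s)\n",
              length(x$times), x$duration,
              ifelse(is.na(x$source_id), "unlabelled", x$source_id)))
  invisible(x)
}

#' Voltage-clamp current trace container
#'
#' Uniformly sampled current recording. Epochs are named, non-overlapping
#' time windows (e.g. baseline / drug) used for per-epoch event summaries.
#'
#' @param samples numeric vector of current samples in pA.
#' @param rate_hz sampling rate in Hz.
#' @param epochs optional named list of `c(start, end)` windows in seconds.
#' @param holding_potential holding potential in mV (metadata only).
#' @return an object of class `current_trace`.
#' @export
current_trace <- function(samples, rate_hz, epochs = NULL,
                          holding_potential = NA_real_) {
  stop_if_not_scalar_pos(rate_hz, "rate_hz")
  samples <- as.numeric(samples)
  dur <- length(samples) / rate_hz
  if (!is.null(epochs)) {
    if (is.null(names(epochs)) || any(!nzchar(names(epochs))))
      stop("epochs must be a named list")
    w <- do.call(rbind, epochs)
    if (any(w[, 1] < 0) || any(w[, 2] > dur + 1e-9) || any(w[, 2] <= w[, 1]))
      stop("epochs must be windows within the trace span")
    o <- order(w[, 1])
    if (any(w[o, 1][-1] < w[o, 2][-nrow(w)] - 1e-12))
      stop("epochs must not overlap")
  }
  structure(list(samples = samples, rate_hz = rate_hz, epochs = epochs,
                 holding_potential = holding_potential),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples @ %g Hz (%.6g s), %d epochs\n",
              length(x$samples), x$rate_hz, length(x$samples) / x$rate_hz,
              length(x$epochs)))
  invisible(x)
}

# Sample times of a current trace (s); sample k covers time (k-1)/rate.
trace_times <- function(trace) {
  (seq_along(trace$samples) - 1) / trace$rate_hz
}

#' Image stack container
#'
#' A time series of frames with acquisition metadata. Data are stored as a
#' 3-D array indexed `[row, col, frame]`.
#'
#' @param data numeric 3-D array `[rows, cols, frames]`.
#' @param frame_rate acquisition rate in Hz.
#' @param um_per_px pixel size in micrometres.
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(data, frame_rate, um_per_px) {
  stop_if_not_scalar_pos(frame_rate, "frame_rate")
  stop_if_not_scalar_pos(um_per_px, "um_per_px")
  if (length(dim(data)) != 3L) stop("`data` must be a 3-D array [row, col, frame]")
  structure(list(data = data, frame_rate = frame_rate, um_per_px = um_per_px),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie_stack> %d x %d px, %d frames @ %g Hz, %g um/px\n",
              d[1], d[2], d[3], x$frame_rate, x$um_per_px))
  invisible(x)
}

n_frames <- function(movie) dim(movie$data)[3]
movie_duration <- function(movie) n_frames(movie) / movie$frame_rate
frame_times <- function(movie) (seq_len(n_frames(movie)) - 1) / movie$frame_rate

#' Detection configuration
#'
#' Bundles the shared detection constants: the SD multiplier used for
#' thresholding, the Gaussian smoothing width applied before border
#' detection, the difference-movie lag, and the minimum peak separation.
#'
#' @param threshold_k threshold in SDs above the mean (default 3).
#' @param gauss_sigma Gaussian smoothing sigma in pixels (default 2).
#' @param diff_lag difference-movie lag in seconds (default 5).
#' @param min_peak_sep minimum separation between detected peaks in seconds.
#' @return an object of class `detection_config`.
#' @export
detection_config <- function(threshold_k = 3, gauss_sigma = 2.0,
                             diff_lag = 5, min_peak_sep = 5) {
  for (nm in c("threshold_k", "gauss_sigma", "diff_lag", "min_peak_sep"))
    stop_if_not_scalar_pos(get(nm), nm)
  structure(list(threshold_k = threshold_k, gauss_sigma = gauss_sigma,
                 diff_lag = diff_lag, min_peak_sep = min_peak_sep),
            class = "detection_config")
}
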