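# Slow running baseline: rolling median over `window_s`, computed on a
# decimated (~100 Hz) copy for speed and interpolated back to every sample.
running_baseline <- function(samples, rate_hz, window_s = 10) {
  dec <- max(1L, floor(rate_hz / 100))
  xs <- samples[seq(1L, length(samples), by = dec)]
  k <- round(window_s * rate_hz / dec)
  k <- max(3L, if (k %% 2 == 0) k + 1L else k)
  k <- min(k, if (length(xs) %% 2 == 0) length(xs) - 1L else length(xs))
  bl <- runmed(xs, k, endrule = "median")
  if (dec == 1L) return(as.numeric(bl))
  approx(x = seq(1L, length(samples), by = dec), y = bl,
         xout = seq_along(samples), rule = 2)$y
}

#' Detect spontaneous inward-current events
#'
#' Events are negative-going excursions beyond `threshold_k` robust noise SDs
#' below a slow running baseline (10 s rolling median). For each event the
#' onset (threshold crossing), signed peak deflection, positive amplitude
#' magnitude, and charge transfer `integral = int (baseline - I) dt` over the
#' event extent (from crossing until the trace first returns within one noise
#' SD of baseline) are reported, plus per-epoch frequency summaries.
#'
#' @param trace a [current_trace]; inward events are negative deflections.
#' @param threshold_k detection threshold in robust noise SDs (default 4).
#' @param min_separation minimum event separation in seconds (default 0.05);
#'   every epoch must be longer than this.
#' @param min_width_s minimum time the trace must spend beyond threshold for
#'   an excursion to count as an event (default 5 ms); rejects isolated
#'   noise samples.
#' @param baseline_window_s running-median window in seconds (default 10).
#' @return a list with `events` (data frame: `onset`, `peak_time`,
#'   `peak_amp` signed pA, `amplitude` positive pA, `integral` pC, `epoch`)
#'   and `epoch_summary` (data frame: `epoch`, `n_events`, `freq_per_min`,
#'   `mean_amplitude`, `mean_integral`).
#' @export
detect_current_events <- function(trace, threshold_k = 4,
                                  min_separation = 0.05,
                                  min_width_s = 0.005,
                                  baseline_window_s = 10) {
  stopifnot(inherits(trace, "current_trace"))
  if (!is.null(trace$epochs)) {
    lens <- vapply(trace$epochs, function(w) w[2] - w[1], numeric(1))
    if (any(lens <= min_separation))
      stop("every epoch must be longer than `min_separation`")
  }
  x <- trace$samples
  rate <- trace$rate_hz
  bl <- running_baseline(x, rate, baseline_window_s)
  resid <- x - bl
  noise <- mad(resid)
  empty <- data.frame(onset = numeric(), peak_time = numeric(),
                      peak_amp = numeric(), amplitude = numeric(),
                      integral = numeric(), epoch = character())
  if (noise == 0 && all(resid == 0))
    return(list(events = empty, epoch_summary = epoch_summary(empty, trace)))
  thr <- -threshold_k * noise
  below <- resid < thr
  if (!any(below))
    return(list(events = empty, epoch_summary = epoch_summary(empty, trace)))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  # merge runs separated by less than min_separation (one event)
  if (length(runs) > 1) {
    gs <- (starts[runs][-1] - ends[runs][-length(runs)]) / rate
    grp <- cumsum(c(1L, as.integer(gs >= min_separation)))
  } else grp <- 1L
  ev <- lapply(split(runs, grp), function(rr) {
    s <- starts[rr[1]]; e <- ends[rr[length(rr)]]
    if (sum(ends[rr] - starts[rr] + 1L) < min_width_s * rate) return(NULL)
    pk <- s + which.min(resid[s:e]) - 1L
    # extent: crossing to first return within one noise SD of baseline
    e2 <- e
    while (e2 < length(resid) && resid[e2 + 1L] < -noise) e2 <- e2 + 1L
    data.frame(onset = (s - 1) / rate, peak_time = (pk - 1) / rate,
               peak_amp = resid[pk], amplitude = -resid[pk],
               integral = sum(-resid[s:e2]) / rate)  # pA*s = pC
  })
  ev <- do.call(rbind, ev)
  if (is.null(ev) || !nrow(ev))
    return(list(events = empty, epoch_summary = epoch_summary(empty, trace)))
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  ev$epoch <- epoch_of(ev$onset, trace$epochs)
  list(events = ev, epoch_summary = epoch_summary(ev, trace))
}

epoch_of <- function(times, epochs) {
  if (is.null(epochs)) return(rep(NA_character_, length(times)))
  out <- rep(NA_character_, length(times))
  for (nm in names(epochs)) {
    w <- epochs[[nm]]
    out[times >= w[1] & times < w[2]] <- nm
  }
  out
}

epoch_summary <- function(events, trace) {
  if (is.null(trace$epochs)) {
    dur_min <- length(trace$samples) / trace$rate_hz / 60
    return(data.frame(epoch = "whole", n_events = nrow(events),
                      freq_per_min = nrow(events) / dur_min,
                      mean_amplitude = if (nrow(events)) mean(events$amplitude) else NA_real_,
                      mean_integral = if (nrow(events)) mean(events$integral) else NA_real_))
  }
  do.call(rbind, lapply(names(trace$epochs), function(nm) {
    w <- trace$epochs[[nm]]
    e <- events[!is.na(events$epoch) & events$epoch == nm, , drop = FALSE]
    data.frame(epoch = nm, n_events = nrow(e),
               freq_per_min = nrow(e) / ((w[2] - w[1]) / 60),
               mean_amplitude = if (nrow(e)) mean(e$amplitude) else NA_real_,
               mean_integral = if (nrow(e)) mean(e$integral) else NA_real_)
  }))
}

#' Holding-current change between two periods
#'
#' Summarizes each period by the 95th percentile of its current samples --
#' robust to brief inward events -- and reports the change `b - a`.
#'
#' @param trace a [current_trace].
#' @param period_a,period_b `c(start, end)` windows in seconds, each at least
#'   10 s long.
#' @param probs percentile used per period (default 0.95).
#' @return a named numeric vector `c(value_a, value_b, change)` in pA.
#' @export
holding_current_change <- function(trace, period_a, period_b, probs = 0.95) {
  stopifnot(inherits(trace, "current_trace"))
  get_period <- function(w, nm) {
    if (length(w) != 2 || w[2] - w[1] < 10)
      stop(sprintf("`%s` must be a window of at least 10 s", nm))
    t <- trace_times(trace)
    s <- trace$samples[t >= w[1] & t < w[2]]
    if (!length(s)) stop(sprintf("`%s` contains no samples", nm))
    s
  }
  a <- unname(quantile(get_period(period_a, "period_a"), probs, type = 7))
  b <- unname(quantile(get_period(period_b, "period_b"), probs, type = 7))
  c(value_a = a, value_b = b, change = b - a)
}

#' Tail-current time series across sweeps
#'
#' Each sweep's tail amplitude is the mean current within the measurement
#' window of the -70 mV step; the series is normalized so the mean over the
#' designated baseline sweeps is 0 pA.
#'
#' @param sweeps list of [current_trace] objects (one voltage-protocol sweep
#'   each).
#' @param sweep_times numeric vector, acquisition time of each sweep in
#'   seconds.
#' @param measure_window `c(start, end)` within each sweep, in seconds.
#' @param baseline_sweeps integer indices of the pre-stimulus sweeps used for
#'   normalization.
#' @param statistic `"mean"` (default) or `"min"` (peak inward) over the
#'   window.
#' @return a data frame with `sweep_time` and `tail_pA` (normalized).
#' @export
tail_current_series <- function(sweeps, sweep_times, measure_window,
                                baseline_sweeps,
                                statistic = c("mean", "min")) {
  statistic <- match.arg(statistic)
  if (missing(baseline_sweeps) || !length(baseline_sweeps))
    stop("baseline sweeps must be specified for normalization")
  if (length(sweeps) != length(sweep_times))
    stop("`sweeps` and `sweep_times` lengths differ")
  amp <- vapply(sweeps, function(tr) {
    stopifnot(inherits(tr, "current_trace"))
    t <- trace_times(tr)
    s <- tr$samples[t >= measure_window[1] & t < measure_window[2]]
    if (!length(s)) stop("a sweep does not contain the measurement window")
    if (statistic == "mean") mean(s) else min(s)
  }, numeric(1))
  if (any(baseline_sweeps < 1 | baseline_sweeps > length(amp)))
    stop("`baseline_sweeps` out of range")
  data.frame(sweep_time = sweep_times,
             tail_pA = amp - mean(amp[baseline_sweeps]))
}
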