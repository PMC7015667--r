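#' Detect spikes in a juxtacellular trace
#'
#' The raw trace is zero-phase high-pass filtered (2nd-order Butterworth) to
#' remove baseline drift, a threshold of `threshold_k` times the robust noise
#' SD (1.4826 x MAD) of the filtered trace is applied, and one spike is
#' reported per suprathreshold excursion at its peak sample. Peaks closer
#' than the refractory interval are merged (larger peak kept).
#'
#' @param trace a [current_trace] (any single-channel recording container).
#' @param highpass_hz high-pass cutoff in Hz (default 10); the sampling rate
#'   must exceed twice the cutoff.
#' @param threshold_k threshold in robust noise SDs (default 5).
#' @param polarity `"positive"`, `"negative"` or `"abs"` excursions.
#' @param refractory_s minimum spike separation in seconds (default 1 ms).
#' @return a [spike_train].
#' @export
detect_spikes <- function(trace, highpass_hz = 10, threshold_k = 5,
                          polarity = c("positive", "negative", "abs"),
                          refractory_s = 0.001) {
  stopifnot(inherits(trace, "current_trace"))
  polarity <- match.arg(polarity)
  if (!length(trace$samples)) stop("empty trace")
  if (trace$rate_hz <= 2 * highpass_hz)
    stop("sampling rate must exceed twice the high-pass cutoff")
  bf <- signal::butter(2, highpass_hz / (trace$rate_hz / 2), type = "high")
  f <- signal::filtfilt(bf, trace$samples)
  f <- switch(polarity, positive = f, negative = -f, abs = abs(f))
  noise <- mad(f)
  thr <- threshold_k * noise
  above <- f > thr
  if (!any(above))
    return(spike_train(numeric(0), length(trace$samples) / trace$rate_hz))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  peaks <- vapply(runs, function(i) {
    s <- starts[i]; e <- ends[i]
    s + which.max(f[s:e]) - 1L
  }, integer(1))
  # refractory merge: keep the larger of peaks closer than refractory_s
  if (length(peaks) > 1) {
    sep <- refractory_s * trace$rate_hz
    ord <- peaks[order(-f[peaks], peaks)]
    keep <- integer(0)
    for (i in ord)
      if (!length(keep) || all(abs(keep - i) >= sep)) keep <- c(keep, i)
    peaks <- sort(keep)
  }
  spike_train((peaks - 1) / trace$rate_hz, length(trace$samples) / trace$rate_hz)
}

# ISI class boundaries (s): mini-burst < MINI_MAX; burst in [MINI_MAX, BURST_MAX]
# (closed at both ends, making the partition total); non-burst > BURST_MAX.
ISI_MINI_MAX <- 0.030
ISI_BURST_MAX <- 1.000

#' Classify interspike intervals
#'
#' Each consecutive interval is labelled `non_burst` (> 1 s), `burst`
#' (30 ms to 1 s, closed interval) or `mini_burst` (< 30 ms).
#'
#' @param train a [spike_train].
#' @return an object of class `isi_classification` with `times`, `intervals`
#'   and `labels` (factor, one label per interval). Fewer than two spikes
#'   yield an empty classification.
#' @export
classify_isis <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  lv <- c("non_burst", "burst", "mini_burst")
  if (length(train$times) < 2)
    return(structure(list(times = train$times, intervals = numeric(0),
                          labels = factor(character(0), levels = lv)),
                     class = "isi_classification"))
  isi <- diff(train$times)
  lab <- ifelse(isi < ISI_MINI_MAX, "mini_burst",
                ifelse(isi <= ISI_BURST_MAX, "burst", "non_burst"))
  structure(list(times = train$times, intervals = isi,
                 labels = factor(lab, levels = lv)),
            class = "isi_classification")
}

#' Detect bursts from classified interspike intervals
#'
#' A burst is a maximal run of consecutive intervals free of `non_burst`
#' labels that contains at least `min_burst_intervals` intervals of the
#' `burst` class. `mini_burst` intervals neither break nor count toward the
#' run, but the spikes they contribute are included in the burst span and
#' spike count; runs may begin or end with mini-burst intervals.
#'
#' @param cls an `isi_classification` from [classify_isis].
#' @param min_burst_intervals qualifying burst-interval count (default 10).
#' @return a data frame with one row per burst: `start`, `end` (s, first and
#'   last spike of the run), `n_spikes`, `duration`.
#' @export
detect_bursts <- function(cls, min_burst_intervals = 10) {
  stopifnot(inherits(cls, "isi_classification"))
  lab <- as.character(cls$labels)
  empty <- data.frame(start = numeric(), end = numeric(),
                      n_spikes = integer(), duration = numeric())
  if (!length(lab)) return(empty)
  in_run <- lab != "non_burst"
  r <- rle(in_run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- empty
  for (i in which(r$values)) {
    s <- starts[i]; e <- ends[i]                   # interval index range
    if (sum(lab[s:e] == "burst") >= min_burst_intervals) {
      t0 <- cls$times[s]; t1 <- cls$times[e + 1L]  # spikes s .. e+1
      out <- rbind(out, data.frame(start = t0, end = t1,
                                   n_spikes = e - s + 2L,
                                   duration = t1 - t0))
    }
  }
  rownames(out) <- NULL
  out
}

#' Burst metrics over an analysis window
#'
#' Reports burst frequency (per minute), mean burst duration, mean spikes per
#' burst, mean action-potential frequency (total spikes / window), and the
#' coefficient of variation of interspike intervals. By default the CV is
#' computed over all ISIs in the window, not only those within bursts.
#'
#' @param bursts data frame from [detect_bursts].
#' @param train the [spike_train] the bursts came from.
#' @param window analysis window length in seconds (default: the train's
#'   duration).
#' @param burst_only_cv compute the ISI CV over within-burst ISIs only.
#' @return a one-row data frame: `burst_freq` (per min), `mean_duration` (s),
#'   `mean_spikes_per_burst`, `mean_ap_freq` (Hz), `isi_cv`. Burst-derived
#'   means are `NA` when no bursts were detected.
#' @export
burst_metrics <- function(bursts, train, window = train$duration,
                          burst_only_cv = FALSE) {
  stop_if_not_scalar_pos(window, "window")
  nb <- nrow(bursts)
  isi <- diff(train$times)
  if (burst_only_cv && nb > 0) {
    keep <- rep(FALSE, length(isi))
    for (i in seq_len(nb)) {
      j <- which(train$times >= bursts$start[i] & train$times <= bursts$end[i])
      if (length(j) > 1) keep[j[-length(j)]] <- TRUE
    }
    isi <- isi[keep]
  }
  cv <- if (length(isi) >= 2 && mean(isi) > 0) sd(isi) / mean(isi) else NA_real_
  data.frame(
    burst_freq = nb / window * 60,
    mean_duration = if (nb) mean(bursts$duration) else NA_real_,
    mean_spikes_per_burst = if (nb) mean(bursts$n_spikes) else NA_real_,
    mean_ap_freq = length(train$times) / window,
    isi_cv = cv)
}

#' Log-binned interspike-interval histogram
#'
#' Bin edges are geometric with `bins_per_decade` bins per decade spanning
#' `range`; counts cover the ISIs falling inside the range.
#'
#' @param train a [spike_train].
#' @param bins_per_decade bins per decade (default 10).
#' @param range two positive values, the ISI range in seconds.
#' @return a data frame with `lower`, `upper`, `mid` (geometric midpoint) and
#'   `count` per bin.
#' @export
isi_log_histogram <- function(train, bins_per_decade = 10,
                              range = c(0.001, 10)) {
  if (any(range <= 0) || range[2] <= range[1])
    stop("`range` must be positive and increasing")
  isi <- diff(train$times)
  l0 <- log10(range[1]); l1 <- log10(range[2])
  nbin <- max(1L, ceiling((l1 - l0) * bins_per_decade))
  edges <- 10^seq(l0, l1, length.out = nbin + 1L)
  inr <- isi[isi >= range[1] & isi <= range[2]]
  cnt <- if (length(inr))
    tabulate(pmin(findInterval(inr, edges, rightmost.closed = TRUE), nbin), nbin)
  else integer(nbin)
  data.frame(lower = edges[-(nbin + 1)], upper = edges[-1],
             mid = sqrt(edges[-(nbin + 1)] * edges[-1]), count = cnt)
}

#' Binned firing rate
#'
#' @param train a [spike_train].
#' @param bin bin width in seconds (default 1).
#' @return numeric vector of length `ceiling(duration / bin)`; each entry is
#'   the spike count in that bin divided by the bin width (Hz).
#' @export
bin_firing_rate <- function(train, bin = 1) {
  stop_if_not_scalar_pos(bin, "bin")
  nb <- ceiling(train$duration / bin)
  if (!length(train$times)) return(numeric(nb))
  idx <- pmin(floor(train$times / bin) + 1L, nb)
  tabulate(idx, nb) / bin
}
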