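#' Specification for a synthetic SGN spike train
#'
#' Describes bursty firing as observed in pre-hearing spiral ganglion
#' neurons: bursts arrive as a Poisson process (thinned so bursts do not
#' overlap), intra-burst intervals are concentrated in the 75-125 ms range
#' (the maximum rate of IHC Ca2+ spike generation), occasional mini-burst
#' doublets ride on intra-burst intervals, and a homogeneous Poisson tonic
#' background is superimposed.
#'
#' @param duration recording duration in seconds.
#' @param burst_rate bursts per minute.
#' @param spikes_per_burst mean spikes per burst; drawn as
#'   `11 + rpois(spikes_per_burst - 11)` so every generated burst satisfies
#'   the >= 10 qualifying-interval definition.
#' @param intra_burst_isi `c(min, max)` of the uniform intra-burst interval
#'   distribution in seconds (default 0.075-0.125; must lie inside the
#'   burst-interval class, 30 ms-1 s).
#' @param tonic_rate homogeneous Poisson background rate in Hz.
#' @param mini_burst_prob probability per intra-burst interval of inserting a
#'   mini-burst doublet (< 30 ms interval).
#' @param seed integer seed; fixed seeds give identical trains.
#' @return an object of class `spike_gen_spec`.
#' @export
spike_gen_spec <- function(duration = 300, burst_rate = 2,
                           spikes_per_burst = 15,
                           intra_burst_isi = c(0.075, 0.125),
                           tonic_rate = 0.2, mini_burst_prob = 0.05,
                           seed = NULL) {
  stop_if_not_scalar_pos(duration, "duration")
  if (burst_rate < 0 || tonic_rate < 0) stop("rates must be non-negative")
  if (spikes_per_burst < 11)
    stop("`spikes_per_burst` must be at least 11 (>= 10 qualifying intervals)")
  if (intra_burst_isi[1] < ISI_MINI_MAX || intra_burst_isi[2] > ISI_BURST_MAX)
    stop("`intra_burst_isi` must lie within the burst-interval class")
  if (mini_burst_prob < 0 || mini_burst_prob > 1)
    stop("`mini_burst_prob` must be a probability")
  structure(list(duration = duration, burst_rate = burst_rate,
                 spikes_per_burst = spikes_per_burst,
                 intra_burst_isi = intra_burst_isi, tonic_rate = tonic_rate,
                 mini_burst_prob = mini_burst_prob, seed = seed),
            class = "spike_gen_spec")
}

#' Generate a synthetic spike train with ground truth
#'
#' @param spec a [spike_gen_spec].
#' @return a list with `train` (a [spike_train]) and `truth` (data frame of
#'   scheduled bursts: `start`, `end`, `n_spikes`; generator parameters
#'   attached as the `"params"` attribute).
#' @export
gen_spike_train <- function(spec) {
  stopifnot(inherits(spec, "spike_gen_spec"))
  with_local_seed(spec$seed, {
    dur <- spec$duration
    max_burst_span <- spec$spikes_per_burst * 2 * spec$intra_burst_isi[2] + 2
    n_bursts <- rpois(1, spec$burst_rate * dur / 60)
    starts <- numeric(0)
    if (n_bursts > 0) {
      # hard-core thinning: resample starts until bursts cannot overlap
      for (attempt in 1:200) {
        cand <- sort(runif(n_bursts, 0, max(dur - max_burst_span, 0)))
        if (n_bursts == 1 || all(diff(cand) > max_burst_span + 1.5)) {
          starts <- cand; break
        }
      }
      if (!length(starts)) {  # fall back to an evenly spaced schedule
        starts <- seq(0, max(dur - max_burst_span, 0), length.out = n_bursts + 2)
        starts <- starts[2:(n_bursts + 1)]
      }
    }
    spikes <- numeric(0)
    truth <- data.frame(start = numeric(), end = numeric(),
                        n_spikes = integer())
    for (s0 in starts) {
      n <- 11L + rpois(1, max(spec$spikes_per_burst - 11, 0))
      isis <- runif(n - 1L, spec$intra_burst_isi[1], spec$intra_burst_isi[2])
      t <- s0 + c(0, cumsum(isis))
      if (spec$mini_burst_prob > 0) {
        add <- which(runif(n - 1L) < spec$mini_burst_prob)
        if (length(add))
          t <- c(t, t[add] + runif(length(add), 0.008, 0.020))
      }
      t <- sort(t[t < dur])
      spikes <- c(spikes, t)
      truth <- rbind(truth, data.frame(start = min(t), end = max(t),
                                       n_spikes = length(t)))
    }
    if (spec$tonic_rate > 0) {
      nt <- rpois(1, spec$tonic_rate * dur)
      spikes <- c(spikes, runif(nt, 0, dur))
    }
    spikes <- sort(unique(spikes))
    if (length(spikes) > 1) {            # enforce strict ordering margin
      keep <- c(TRUE, diff(spikes) > 1e-5)
      spikes <- spikes[keep]
    }
    attr(truth, "params") <- unclass(spec)
    list(train = spike_train(spikes, dur, "synthetic"), truth = truth)
  })
}
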