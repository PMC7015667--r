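#' Generate a synthetic voltage-clamp current trace with ground truth
#'
#' Emulates spontaneous inward currents recorded from inner supporting cells:
#' events have instantaneous onset and single-exponential decay, amplitudes
#' are drawn log-normal (heavy-tailed event sizes), a slow linear baseline
#' drift can be added, and Gaussian noise is superimposed. Event onsets
#' arrive as a Poisson process thinned to a minimum separation so events
#' remain resolvable.
#'
#' @param event_rate events per minute.
#' @param amp_mean mean event amplitude in pA (deflections are negative).
#' @param tau_decay decay time constant in seconds.
#' @param noise_sd Gaussian noise SD in pA (>= 0).
#' @param drift linear baseline drift in pA/s.
#' @param duration trace duration in seconds.
#' @param rate_hz sampling rate in Hz.
#' @param baseline_pA standing holding current in pA.
#' @param amp_sdlog log-normal shape parameter of amplitudes.
#' @param min_separation minimum event onset separation in seconds.
#' @param epochs optional epochs passed to [current_trace].
#' @param seed integer seed.
#' @return a list with `trace` (a [current_trace]) and `truth` (data frame:
#'   `onset`, `amplitude` positive pA, `tau`; parameters attached as the
#'   `"params"` attribute).
#' @export
gen_current_trace <- function(event_rate, amp_mean = 100, tau_decay = 0.2,
                              noise_sd = 4, drift = 0, duration = 600,
                              rate_hz = 1000, baseline_pA = -50,
                              amp_sdlog = 0.4, min_separation = 1.5,
                              epochs = NULL, seed = NULL) {
  stop_if_not_scalar_pos(duration, "duration")
  stop_if_not_scalar_pos(rate_hz, "rate_hz")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (event_rate < 0) stop("`event_rate` must be non-negative")
  with_local_seed(seed, {
    n <- round(duration * rate_hz)
    t <- (seq_len(n) - 1) / rate_hz
    x <- baseline_pA + drift * t
    n_ev <- rpois(1, event_rate * duration / 60)
    truth <- data.frame(onset = numeric(), amplitude = numeric(),
                        tau = numeric())
    if (n_ev > 0) {
      onsets <- numeric(0)
      for (attempt in 1:200) {
        cand <- sort(runif(n_ev, 1, duration - 5 * tau_decay))
        if (n_ev == 1 || all(diff(cand) > min_separation)) { onsets <- cand; break }
      }
      if (!length(onsets)) {
        onsets <- seq(1, duration - 5 * tau_decay, length.out = n_ev + 2)
        onsets <- onsets[2:(n_ev + 1)]
      }
      amps <- rlnorm(n_ev, log(amp_mean) - amp_sdlog^2 / 2, amp_sdlog)
      for (i in seq_len(n_ev)) {
        k0 <- floor(onsets[i] * rate_hz) + 1L
        kk <- k0:min(n, k0 + ceiling(8 * tau_decay * rate_hz))
        x[kk] <- x[kk] - amps[i] * exp(-(t[kk] - t[k0]) / tau_decay)
      }
      truth <- data.frame(onset = (floor(onsets * rate_hz)) / rate_hz,
                          amplitude = amps, tau = tau_decay)
    }
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    attr(truth, "params") <- list(event_rate = event_rate, amp_mean = amp_mean,
                                  tau_decay = tau_decay, noise_sd = noise_sd,
                                  drift = drift, duration = duration,
                                  rate_hz = rate_hz, baseline_pA = baseline_pA,
                                  seed = seed)
    list(trace = current_trace(x, rate_hz, epochs = epochs,
                               holding_potential = -80),
         truth = truth)
  })
}
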