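# Independent oracles and fixture builders shared across the suite.

# Brute-force burst enumeration over an ISI label sequence: every maximal
# contiguous window free of non_burst labels, kept iff it holds at least
# `min_bi` burst labels. Written as an exhaustive window scan, independent
# of the run-length implementation in the package.
oracle_bursts_from_labels <- function(labels, times, min_bi = 10) {
  n <- length(labels)
  out <- list()
  i <- 1
  while (i <= n) {
    if (labels[i] == "non_burst") { i <- i + 1; next }
    j <- i
    while (j < n && labels[j + 1] != "non_burst") j <- j + 1
    # window [i, j] is maximal; check left/right maximality explicitly
    stopifnot(i == 1 || labels[i - 1] == "non_burst",
              j == n || labels[j + 1] == "non_burst")
    if (sum(labels[i:j] == "burst") >= min_bi)
      out[[length(out) + 1]] <- data.frame(
        start = times[i], end = times[j + 1],
        n_spikes = as.integer(j - i + 2), duration = times[j + 1] - times[i])
    i <- j + 1
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start = numeric(), end = numeric(), n_spikes = integer(),
                  duration = numeric())
}

# Build spike times whose consecutive ISIs realize a given label sequence.
times_for_labels <- function(labels) {
  isi <- vapply(labels, function(l) switch(l, non_burst = 1.5, burst = 0.1,
                                           mini_burst = 0.01), numeric(1))
  cumsum(c(0.5, isi))
}

random_label_seq <- function(n, p = c(non_burst = 0.2, burst = 0.6,
                                      mini_burst = 0.2)) {
  sample(names(p), n, replace = TRUE, prob = p)
}

# Naive 2-D Gaussian convolution (direct double loop over kernel offsets),
# independent of EBImage, zero-padded boundary.
oracle_gaussian_smooth <- function(m, sigma) {
  r <- ceiling(3 * sigma)
  g <- outer(-r:r, -r:r, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  g <- g / sum(g)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2 * r, nc + 2 * r)
  pad[(r + 1):(r + nr), (r + 1):(r + nc)] <- m
  out <- matrix(0, nr, nc)
  for (di in -r:r) for (dj in -r:r)
    out <- out + g[di + r + 1, dj + r + 1] *
      pad[(r + 1 + di):(r + nr + di), (r + 1 + dj):(r + nc + dj)]
  out
}

# Binary disk mask centred in a square frame.
disk_mask <- function(n, cx, cy, r) {
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), n), n, n)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# Jittered-grid event times with guaranteed spacing (for schedules where a
# Poisson process would be too dense to thin).
jittered_times <- function(n, lo, hi, jitter = 1) {
  base <- seq(lo, hi, length.out = n)
  base + runif(n, -jitter, jitter)
}

# Small two-lobe IC fixture used by the bilateral and event tests.
make_ic_fixture <- function(n_events, ratio, seed, fps = 10, dur_s = 300,
                            amplitude = 0.15, noise_sd = 3) {
  H <- 48; W <- 64
  geom <- list(left = scan_geometry(c(4, 24), 0, length_px = 28, width_px = 20),
               right = scan_geometry(c(36, 24), 0, length_px = 28, width_px = 20))
  sch <- data.frame(
    time = seq(8, dur_s - 8, length.out = n_events),
    lobe = rep(c("left", "right"), length.out = n_events),
    amplitude = amplitude, position_um = 14, width_um = 10, duration = 1.2)
  ms <- movie_gen_spec(c(H, W, fps * dur_s), fps, 1, sch, noise_sd = noise_sd,
                       bilateral_ratio = ratio, geometry = geom, seed = seed)
  g <- gen_widefield_movie(ms, "IC")
  rois <- roi_set(list(roi_rect("left", 1, 1, W / 2, H, "lobe"),
                       roi_rect("right", W / 2 + 1, 1, W / 2, H, "lobe")))
  list(gen = g, rois = rois, dffm = dff(g$movie))
}
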