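test_that("ISI classes follow the boundary rule", {
  tr <- spike_train(cumsum(c(0.5, 0.5, 2.0, 0.010, 0.030, 1.000, 1.001,
                             0.0299)), 10)
  cls <- classify_isis(tr)
  expect_identical(as.character(cls$labels),
                   c("burst", "non_burst", "mini_burst", "burst", "burst",
                     "non_burst", "mini_burst"))
  expect_length(cls$labels, length(tr$times) - 1)
  # fewer than two spikes: empty classification, not an error
  expect_length(classify_isis(spike_train(1.0, 10))$labels, 0)
})

test_that("burst detection matches the definition on forced cases", {
  # 11 spikes, all ISIs 0.1 s -> one burst of 11 spikes lasting 1 s
  tr <- spike_train(seq(0, by = 0.1, length.out = 11), 10)
  b <- detect_bursts(classify_isis(tr))
  expect_identical(nrow(b), 1L)
  expect_identical(b$n_spikes, 11L)
  expect_equal(b$duration, 1.0)
  # 10 spikes (9 qualifying intervals) -> no burst
  tr9 <- spike_train(seq(0, by = 0.1, length.out = 10), 10)
  expect_identical(nrow(detect_bursts(classify_isis(tr9))), 0L)
  # interleaved mini-burst: 12 spikes, labels burst x5, mini, burst x5
  isis <- c(rep(0.1, 5), 0.01, rep(0.1, 5))
  tr12 <- spike_train(cumsum(c(0.5, isis)), 10)
  b12 <- detect_bursts(classify_isis(tr12))
  expect_identical(nrow(b12), 1L)
  expect_identical(b12$n_spikes, 12L)
})

test_that("burst detection agrees with the brute-force oracle on random label sequences", {
  set.seed(101)
  for (rep in 1:300) {
    labels <- random_label_seq(sample(5:60, 1))
    times <- times_for_labels(labels)
    tr <- spike_train(times, max(times) + 1)
    cls <- classify_isis(tr)
    expect_identical(as.character(cls$labels), unname(labels))
    got <- detect_bursts(cls)
    want <- oracle_bursts_from_labels(labels, times)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("time-shifting a train shifts burst spans and preserves metrics", {
  g <- gen_spike_train(spike_gen_spec(duration = 300, burst_rate = 3,
                                      tonic_rate = 0.3, seed = 12))
  b0 <- detect_bursts(classify_isis(g$train))
  shifted <- spike_train(g$train$times + 2.5, g$train$duration + 3)
  b1 <- detect_bursts(classify_isis(shifted))
  expect_equal(b1$start, b0$start + 2.5)
  expect_equal(b1$end, b0$end + 2.5)
  m0 <- burst_metrics(b0, g$train, window = 300)
  m1 <- burst_metrics(b1, shifted, window = 300)
  expect_equal(m0, m1)
})

test_that("merging trains separated by silence unions their burst lists", {
  g1 <- gen_spike_train(spike_gen_spec(duration = 120, burst_rate = 3,
                                       tonic_rate = 0, seed = 4))
  g2 <- gen_spike_train(spike_gen_spec(duration = 120, burst_rate = 3,
                                       tonic_rate = 0, seed = 5))
  offset <- 120 + 5  # > 1 s of silence between the two trains
  merged <- spike_train(c(g1$train$times, g2$train$times + offset), 250)
  bm <- detect_bursts(classify_isis(merged))
  b1 <- detect_bursts(classify_isis(g1$train))
  b2 <- detect_bursts(classify_isis(g2$train))
  expect_identical(nrow(bm), nrow(b1) + nrow(b2))
  expect_equal(bm$start, c(b1$start, b2$start + offset))
})

test_that("burst metrics: frequency units, CV behaviour, empty-burst handling", {
  # 5 bursts in 300 s -> 1 burst per minute
  b <- data.frame(start = 1:5 * 50, end = 1:5 * 50 + 1, n_spikes = 11L,
                  duration = 1)
  tr <- spike_train(seq(0.1, 299, length.out = 100), 300)
  m <- burst_metrics(b, tr, window = 300)
  expect_equal(m$burst_freq, 1.0)
  # perfectly periodic train: CV exactly 0
  per <- spike_train(seq(0.5, 99.5, by = 0.5), 100)
  expect_identical(burst_metrics(b, per, window = 100)$isi_cv, 0)
  # zero bursts: burst-derived means are missing, not zero
  m0 <- burst_metrics(b[0, ], tr, window = 300)
  expect_true(is.na(m0$mean_duration) && is.na(m0$mean_spikes_per_burst))
  expect_identical(m0$burst_freq, 0)
})

test_that("Poisson-train ISI CV is 1", {
  set.seed(99)
  isi <- rexp(10000, rate = 5)
  tr <- spike_train(cumsum(isi), sum(isi) + 1)
  cv <- burst_metrics(data.frame(start = numeric(), end = numeric(),
                                 n_spikes = integer(), duration = numeric()),
                      tr, window = tr$duration)$isi_cv
  expect_equal(cv, 1, tolerance = 0.05)
})

test_that("log-binned ISI histogram has geometric edges and exact counts", {
  tr <- spike_train(c(0.5, 0.6), 10)
  h <- isi_log_histogram(tr, bins_per_decade = 10, range = c(0.001, 10))
  expect_identical(sum(h$count), 1L)
  expect_identical(sum(h$count[h$lower <= 0.1 & h$upper >= 0.1]), 1L)
  expect_equal(h$upper[-nrow(h)] / h$lower[-nrow(h)],
               h$upper[-1] / h$lower[-1], tolerance = 1e-9)
  # counts sum to the number of in-range ISIs for random trains
  set.seed(3)
  for (rep in 1:20) {
    isis <- rexp(200, 3)
    trn <- spike_train(cumsum(isis), sum(isis) + 1)
    real_isis <- diff(trn$times)
    rng <- c(0.005, 5)
    h2 <- isi_log_histogram(trn, 8, rng)
    expect_identical(sum(h2$count),
                     sum(real_isis >= rng[1] & real_isis <= rng[2]))
  }
  # a burst-interval train concentrates all mass inside its range
  trb <- spike_train(cumsum(runif(200, 0.075, 0.125)), 30)
  h3 <- isi_log_histogram(trb, 10, c(0.001, 10))
  expect_identical(sum(h3$count[h3$upper >= 0.075 & h3$lower <= 0.125]),
                   199L)
  expect_error(isi_log_histogram(trb, 10, c(-1, 10)), "positive")
})

test_that("binned firing rate has the right length and conserves spike count", {
  tr <- spike_train(seq(0.05, 9.95, length.out = 10), 10)
  r <- bin_firing_rate(tr, 1)
  expect_length(r, 10)
  expect_equal(sum(r) * 1, 10)
  expect_identical(bin_firing_rate(spike_train(numeric(0), 7.5), 1),
                   numeric(8))
  set.seed(8)
  for (rep in 1:10) {
    g <- gen_spike_train(spike_gen_spec(duration = 61.3, burst_rate = 4,
                                        tonic_rate = 1, seed = rep))
    bin <- sample(c(0.5, 1, 2), 1)
    expect_equal(sum(bin_firing_rate(g$train, bin)) * bin,
                 length(g$train$times))
  }
})

test_that("spike detection recovers injected spikes and is threshold-stable", {
  set.seed(21)
  rate <- 10000
  x <- numeric(rate * 10)
  tk <- seq(0.5, 9.5, by = 0.45)[1:20]
  for (t0 in tk) {  # ~0.5 ms wide action potentials
    k <- round(t0 * rate)
    x[k:(k + 15)] <- x[k:(k + 15)] + 60 * exp(-(0:15) / 3)
  }
  drift <- 15 * sin(2 * pi * 0.4 * seq_len(rate * 10) / rate)
  noise <- rnorm(rate * 10, 0, 1)   # recording noise floor
  tr <- current_trace(x + drift + noise, rate)
  st5 <- detect_spikes(tr, threshold_k = 5)
  st7 <- detect_spikes(tr, threshold_k = 7)
  expect_length(st5$times, 20)
  expect_identical(length(st5$times), length(st7$times))
  expect_lt(max(abs(st5$times - (tk - 1 / rate))), 1.5 / rate)
  # flat trace: no spikes; empty trace errors
  expect_length(detect_spikes(current_trace(numeric(1000), rate))$times, 0)
  expect_error(detect_spikes(current_trace(numeric(0), rate)), "empty")
})
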