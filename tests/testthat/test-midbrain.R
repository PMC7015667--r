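test_that("IC event detection applies the fixed 2 percent threshold", {
  fx <- make_ic_fixture(n_events = 6, ratio = 0, seed = 3, dur_s = 60,
                        amplitude = 0.10)
  ev <- detect_ic_events(fx$dffm, fx$rois)
  expect_identical(nrow(ev), 6L)              # 10% events all detected
  fx_low <- make_ic_fixture(n_events = 6, ratio = 0, seed = 3, dur_s = 60,
                            amplitude = 0.012) # ~1% at the band: subthreshold
  ev_low <- detect_ic_events(fx_low$dffm, fx_low$rois)
  expect_identical(nrow(ev_low), 0L)
  bad_rois <- roi_set(list(roi_rect("left", 1, 1, 10, 10, "lobe")))
  expect_error(detect_ic_events(fx$dffm, bad_rois), "left.*right|right")
})

test_that("half-width of a symmetric triangular event is half its base", {
  # build a lobe trace directly: triangle of base 4 s on a flat movie
  fps <- 10
  a <- array(1000, c(10, 20, 60 * fps))
  tri <- c(seq(0, 1, length.out = 2 * fps + 1),
           seq(1, 0, length.out = 2 * fps + 1)[-1])
  kk <- 300 + seq_along(tri)
  for (i in seq_along(tri)) a[, , kk[i]] <- 1000 * (1 + 0.08 * tri[i])
  dffm <- dff(movie_stack(a, fps, 1))
  rois <- roi_set(list(roi_rect("left", 1, 1, 10, 10, "lobe"),
                       roi_rect("right", 11, 1, 10, 10, "lobe")))
  ev <- detect_ic_events(dffm, rois)
  expect_identical(nrow(ev), 2L)  # both lobes see the whole-frame event
  expect_equal(ev$half_width, rep(2, 2), tolerance = 0.05)
  expect_equal(ev$amplitude_pct, rep(8, 2), tolerance = 0.02)
})

test_that("bilateral pairing: ratio, dominance, and unmatched events", {
  ev <- data.frame(time = c(10, 10.1, 30, 50, 50.2),
                   lobe = c("left", "right", "left", "right", "left"),
                   amplitude_pct = c(10, 6, 5, 4, 4),
                   half_width = 1, frame = 1:5)
  m <- match_bilateral(ev, window = 0.5)
  expect_identical(nrow(m$pairs), 2L)
  expect_equal(m$pairs$ratio[1], 0.6)
  expect_identical(m$pairs$dominant_lobe[1], "left")
  expect_equal(m$pairs$ratio[2], 1.0)   # equal amplitudes: full synchrony
  expect_identical(nrow(m$unmatched), 1L)
  expect_equal(m$unmatched$time, 30)
  # symmetry under lobe relabelling
  ev2 <- ev
  ev2$lobe <- ifelse(ev$lobe == "left", "right", "left")
  m2 <- match_bilateral(ev2, window = 0.5)
  expect_equal(m2$pairs$ratio, m$pairs$ratio)
  expect_true(all(m$pairs$ratio > 0 & m$pairs$ratio <= 1))
})

test_that("generator bilateral ratio is recovered from paired events", {
  fx <- make_ic_fixture(n_events = 25, ratio = 0.6, seed = 5, dur_s = 150)
  ev <- detect_ic_events(fx$dffm, fx$rois)
  m <- match_bilateral(ev)
  expect_gte(nrow(m$pairs), 23)
  expect_equal(mean(m$pairs$ratio), 0.6, tolerance = 0.05 / 0.6)
})

test_that("whole-field flashes are excluded, confined bands retained", {
  fps <- 10
  a <- array(1000, c(48, 64, 40 * fps))
  # confined band on the left lobe at t = 10 s
  band <- outer(seq_len(48), seq_len(32),
                function(r, c) abs(c - 16) <= 2) # ~16% of the lobe
  kk10 <- 10 * fps + seq_len(10)
  for (k in kk10) {
    fr <- a[, , k]
    fr[, 1:32][band] <- 1250   # lobe-mean ~3.9%, above the 2% threshold
    a[, , k] <- fr
  }
  # whole-field flash at t = 25 s
  kk25 <- 25 * fps + seq_len(10)
  a[, , kk25] <- 1100
  dffm <- dff(movie_stack(a, fps, 1))
  rois <- roi_set(list(roi_rect("left", 1, 1, 32, 48, "lobe"),
                       roi_rect("right", 33, 1, 32, 48, "lobe")))
  ev <- detect_ic_events(dffm, rois)
  kept <- exclude_global_events(ev, dffm, rois, coverage_frac = 0.8)
  expect_true(any(abs(ev$time - 25) < 1.5))      # flash was detected...
  expect_false(any(abs(kept$time - 25) < 1.5))   # ...and then excluded
  expect_true(any(abs(kept$time - 10) < 1.5))    # band retained
  expect_error(exclude_global_events(ev, dffm, rois, coverage_frac = 0),
               "coverage_frac")
})

test_that("line scan of a uniform frame is flat and band peaks localize", {
  fps <- 2
  geom <- scan_geometry(c(25, 22), 55)
  a <- array(1000, c(160, 160, 30))
  a[, , 15] <- 1080
  dffm <- dff(movie_stack(a, fps, 20))
  scan <- tonotopic_linescan(dffm, geom)
  expect_identical(nrow(scan$values), 125L)
  expect_equal(diff(range(scan$values[, 15])), 0, tolerance = 1e-9)
  expect_equal(max(scan$values[, 15]), 8, tolerance = 1e-6)
  # out-of-bounds rectangle errors
  expect_error(tonotopic_linescan(dffm, scan_geometry(c(150, 150), 55)),
               "outside")
})

test_that("injected Gaussian bands are recovered at their positions", {
  fps <- 2
  geom <- scan_geometry(c(25, 22), 55)
  pos <- c(500, 1500)
  sch <- data.frame(time = c(30, 90), lobe = "left", amplitude = 0.15,
                    position_um = pos, width_um = 150, duration = 2)
  ms <- movie_gen_spec(c(160, 160, 300), fps, 20, sch, noise_sd = 3,
                       geometry = list(left = geom), seed = 7)
  g <- gen_widefield_movie(ms, "IC")
  scan <- tonotopic_linescan(dff(g$movie), geom)
  pk <- detect_band_peaks(scan, 3)
  expect_identical(nrow(pk), 2L)
  expect_lt(max(abs(sort(pk$position_um) - pos)), 20 + 1e-9)  # one sample
  # uniform scans yield no peaks
  flat <- scan
  flat$values[] <- 1
  expect_identical(nrow(detect_band_peaks(flat, 3)), 0L)
})

test_that("spatial histogram splits, excludes, and is order-invariant", {
  pk <- data.frame(position_um = c(rep(100, 10), 700, 820),
                   time = seq_len(12), amplitude_pct = 5,
                   pos_idx = 1, frame = seq_len(12))
  h <- spatial_event_histogram(pk, duration_min = 10, split_um = 500)
  expect_identical(h$n_lateral, 10L)
  expect_identical(h$n_medial, 2L)
  expect_identical(sum(h$histogram$count), 12L)
  expect_equal(h$lateral_freq_per_min, 1.0)
  # histogram is invariant to time permutation of events
  pk2 <- pk[sample(nrow(pk)), ]
  h2 <- spatial_event_histogram(pk2, 10, 500)
  expect_identical(h2$histogram$count, h$histogram$count)
  # exclusion zone around the single-band locus removes its edge events
  h3 <- spatial_event_histogram(pk, 10, 500, exclusion_center_um = 780,
                                exclusion_halfwidth_um = 90)
  expect_identical(h3$n_excluded, 2L)
  expect_identical(sum(h3$histogram$count), 10L)
  expect_error(spatial_event_histogram(pk, 10, split_um = -5), "split_um")
})

test_that("retinal wave definition is enforced strictly", {
  fps <- 5
  H <- 150; W <- 200
  mk_sc <- function(n_px, dur) {
    sch <- data.frame(time = 10, lobe = "left", duration = dur,
                      n_px = n_px, amplitude = 0.3)
    ms <- movie_gen_spec(c(H, W, 100), fps, 8, sch, noise_sd = 4,
                         geometry = list(left = roi_rect("left", 1, 1, W, H,
                                                         "lobe"),
                                         down_factor = 5),
                         seed = 13)
    gen_widefield_movie(ms, "SC")$movie
  }
  rois <- roi_set(list(roi_rect("left", 1, 1, 200, 150, "lobe")))
  # exactly 5 active pixels: rejected (needs more than five)
  res5 <- detect_retinal_waves(mk_sc(5, 2), rois)
  expect_identical(nrow(res5$waves), 0L)
  # 0.8 s of >5 pixels: rejected (needs > 1 s)
  res08 <- detect_retinal_waves(mk_sc(10, 0.8), rois)
  expect_identical(nrow(res08$waves), 0L)
  # 10 pixels for 2 s: exactly one wave of duration 2 s
  res2 <- detect_retinal_waves(mk_sc(10, 2), rois)
  expect_identical(nrow(res2$waves), 1L)
  expect_equal(res2$waves$duration, 2, tolerance = 1e-9)
  # undersized ROI errors
  small <- roi_set(list(roi_rect("left", 1, 1, 100, 80, "lobe")))
  expect_error(detect_retinal_waves(mk_sc(10, 2), small), "smaller")
})

test_that("scheduled waves are recovered with durations within one frame", {
  fps <- 5
  set.seed(2)
  n <- 8
  t0s <- jittered_times(n, 4, 95, 1.5)
  durs <- runif(n, 1.2, 2.4)
  sch <- data.frame(time = t0s, lobe = "left", duration = durs, n_px = 10,
                    amplitude = 0.3)
  ms <- movie_gen_spec(c(150, 200, 110 * fps), fps, 8, sch, noise_sd = 4,
                       geometry = list(left = roi_rect("left", 1, 1, 200, 150,
                                                       "lobe"),
                                       down_factor = 5),
                       seed = 11)
  g <- gen_widefield_movie(ms, "SC")
  rois <- roi_set(list(roi_rect("left", 1, 1, 200, 150, "lobe")))
  res <- detect_retinal_waves(g$movie, rois)
  expect_identical(nrow(res$waves), as.integer(n))
  for (i in seq_len(n)) {
    j <- which.min(abs(res$waves$start - g$truth$time[i]))
    expect_lte(abs(res$waves$duration[j] - g$truth$measured_duration[i]),
               1 / fps + 1e-9)
  }
  expect_true(all(res$waves$duration > 1))
  expect_lte(sum(res$waves$duration), 110)
})
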