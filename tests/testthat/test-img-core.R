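test_that("dF/F is zero on constant movies and scale invariant", {
  m <- movie_stack(array(250, c(8, 9, 30)), 10, 1)
  d <- dff(m)
  expect_true(all(d$dff == 0))
  expect_true(all(d$f0 == 250))
  set.seed(2)
  m2 <- movie_stack(array(runif(8 * 9 * 30, 50, 150), c(8, 9, 30)), 10, 1)
  d2 <- dff(m2)
  m2x <- movie_stack(2 * m2$data, 10, 1)
  expect_equal(dff(m2x)$dff, d2$dff, tolerance = 1e-12)
})

test_that("per-pixel F0 is the 5th percentile (direct quantile oracle)", {
  set.seed(11)
  m <- movie_stack(array(rlnorm(10 * 10 * 99, log(100), 0.3),
                         c(10, 10, 99)), 10, 1)
  d <- dff(m)
  for (i in 1:10) for (j in 1:10)
    expect_equal(d$f0[i, j],
                 unname(quantile(m$data[i, j, ], 0.05, type = 7)))
  # a single bright frame on a flat trace: F0 = baseline, peak dF/F = 0.5
  tr <- c(rep(100, 99), 150)
  a <- array(100, c(2, 2, 100)); a[1, 1, ] <- tr
  d2 <- dff(movie_stack(a, 1, 1))
  expect_equal(d2$f0[1, 1], 100)
  expect_equal(max(d2$dff[1, 1, ]), 0.5)
  # zero-baseline pixels are rejected with advice
  a0 <- array(0, c(2, 2, 30))
  expect_error(dff(movie_stack(a0, 1, 1)), "offset")
})

test_that("bleach correction flattens an exponential frame-mean decay", {
  tt <- 0:299
  decay <- 120 * exp(-tt / 80)
  a <- array(rep(500 + decay, each = 25), c(5, 5, 300))
  bc <- bleach_correct(movie_stack(a, 1, 1))
  fm <- apply(bc$data, 3, mean)
  expect_lt(diff(range(fm)), 0.5)
  fit <- attr(bc, "bleach_fit")
  expect_equal(unname(fit["tau"]), 80, tolerance = 0.02)
  # constant movies are returned unchanged (with a warning about no decay)
  flat <- movie_stack(array(500, c(5, 5, 50)), 1, 1)
  expect_warning(bc2 <- bleach_correct(flat), "decay|failed")
  expect_equal(bc2$data, flat$data)
})

test_that("bleach correction preserves event amplitudes on a mildly bleached movie", {
  # events in the first half of a movie whose bleach tau is 10x its length
  sch <- data.frame(time = c(20, 60, 100), cx = c(10, 20, 15),
                    cy = c(10, 20, 15), radius_px = 5, amplitude = 0.2,
                    duration = 10)
  ms <- movie_gen_spec(c(30, 30, 300), 1, 1, sch, bleach_tau = 3000,
                       noise_sd = 0.5, seed = 6)
  g <- gen_widefield_movie(ms, "crenation")
  d <- dff(bleach_correct(g$movie))
  for (i in seq_len(nrow(sch))) {
    px <- d$dff[sch$cy[i], sch$cx[i], ]
    expect_equal(max(px), 0.2, tolerance = 0.05)
  }
})

test_that("difference movie subtracts lagged frames", {
  set.seed(3)
  a <- array(runif(6 * 6 * 40, 90, 110), c(6, 6, 40))
  m <- movie_stack(a, 1, 1)
  dm <- difference_movie(m, 5)
  expect_identical(dim(dm$data)[3], 35L)
  # direct subtraction oracle
  for (k in c(1, 17, 35))
    expect_equal(dm$data[, , k], a[, , k + 5] - a[, , k])
  # static movie: all-zero difference
  st <- movie_stack(array(77, c(6, 6, 40)), 1, 1)
  expect_true(all(difference_movie(st, 5)$data == 0))
  # a single step change appears only while the lag window crosses it
  stp <- array(100, c(4, 4, 30)); stp[, , 16:30] <- 130
  dms <- difference_movie(movie_stack(stp, 1, 1), 5)
  nz <- which(apply(dms$data, 3, function(f) any(f != 0)))
  expect_identical(nz, 11:15)
  expect_error(difference_movie(movie_stack(stp[, , 1:4, drop = FALSE], 1, 1),
                                5), "shorter")
})

test_that("global threshold mask matches the normal tail on Gaussian noise", {
  set.seed(14)
  m <- movie_stack(array(rnorm(50 * 50 * 40), c(50, 50, 40)), 1, 1)
  mask <- threshold_mask(m, 3)
  p_hat <- mean(mask)
  p <- pnorm(3, lower.tail = FALSE)  # 0.00135
  n <- length(mask)
  expect_lt(abs(p_hat - p), 4 * sqrt(p * (1 - p) / n))
  # constant stack: empty mask
  expect_false(any(threshold_mask(movie_stack(array(5, c(4, 4, 10)), 1, 1))))
  # one extreme pixel is exactly the active set
  a <- array(rnorm(20 * 20 * 10), c(20, 20, 10))
  a[7, 9, 3] <- 10 * sd(a) + mean(a)
  mk <- threshold_mask(movie_stack(a, 1, 1), 3)
  strong <- which(mk, arr.ind = TRUE)
  expect_true(any(strong[, 1] == 7 & strong[, 2] == 9 & strong[, 3] == 3))
})

test_that("region areas equal the smoothed-mask pixel-count oracle", {
  # filled disk: area within 15% of pi r^2, and exactly the oracle's count
  mask <- disk_mask(64, 32, 32, 10)
  reg <- region_areas(mask, gauss_sigma = 2, um_per_px = 1)
  expect_identical(nrow(reg), 1L)
  expect_equal(reg$area_um2, pi * 100, tolerance = 0.15)
  oracle_px <- sum(oracle_gaussian_smooth(mask * 1, 2) >= 0.5)
  expect_identical(reg$n_px, oracle_px)
  expect_identical(reg$area_um2, oracle_px * 1)
  # scale factor applies squared
  reg2 <- region_areas(mask, gauss_sigma = 2, um_per_px = 2)
  expect_identical(reg2$area_um2, oracle_px * 4)
  # sigma -> 0: single pixel survives, area = (um/px)^2
  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  r1 <- region_areas(single, gauss_sigma = 0, um_per_px = 2)
  expect_equal(r1$area_um2, 4)
  # two disks separated by much more than 6 sigma: two regions
  two <- disk_mask(80, 20, 20, 6) | disk_mask(80, 60, 60, 6)
  expect_identical(nrow(region_areas(two, 2, 1)), 2L)
  # diagonal-touching pixels are one 8-connected region
  diag2 <- matrix(FALSE, 6, 6); diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  expect_identical(nrow(region_areas(diag2, gauss_sigma = 0, um_per_px = 1)),
                   1L)
  expect_identical(nrow(region_areas(matrix(FALSE, 5, 5), 2, 1)), 0L)
})

test_that("peak detection honours the threshold and greedy separation", {
  # triangular pulse above threshold: one peak at the apex
  x <- c(rep(0, 10), seq(0, 5, by = 1), seq(4, 0, by = -1), rep(0, 10))
  pk <- find_peaks_threshold(x, 2, min_sep = 0, rate_hz = 1)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$value, 5)
  # flat trace: nothing
  expect_identical(nrow(find_peaks_threshold(rep(1, 50), 2)), 0L)
  # two pulses closer than min_sep: keep the larger (5 over 3)
  y <- rep(0, 60)
  y[20 + -2:2] <- c(1, 3, 5, 3, 1)
  y[26 + -2:2] <- pmax(y[26 + -2:2], c(1, 2, 3, 2, 1))
  pk2 <- find_peaks_threshold(y, 0.5, min_sep = 10, rate_hz = 1)
  expect_identical(nrow(pk2), 1L)
  expect_identical(pk2$value, 5)
  # exhaustive small-case check against a direct plateau-aware scan
  oracle_peaks <- function(z, thr) {
    r <- rle(z); k <- length(r$values); n_pk <- 0L
    if (k >= 3) for (i in 2:(k - 1))
      if (r$values[i] > thr && r$values[i] > r$values[i - 1] &&
          r$values[i] > r$values[i + 1]) n_pk <- n_pk + 1L
    n_pk
  }
  set.seed(6)
  for (rep in 1:50) {
    z <- round(runif(40, 0, 4), 1)
    got <- find_peaks_threshold(z, 2, min_sep = 0, rate_hz = 1)
    expect_identical(nrow(got), oracle_peaks(z, 2))
  }
})
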