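#' Normalize an image stack to dF/F0
#'
#' The per-pixel baseline F0 is the 5th percentile of that pixel's intensity
#' over time (linear interpolation between order statistics), and the
#' normalized movie is `(F - F0) / F0`. Values are dimensionless fractions;
#' multiply by 100 for percent dF/F0.
#'
#' @param movie a [movie_stack].
#' @param f0_quantile baseline quantile over time (default 0.05).
#' @return an object of class `dff_movie` with elements `dff` (array, same
#'   shape as the input data), `f0` (matrix, per-pixel baseline),
#'   `frame_rate`, `um_per_px`.
#' @export
dff <- function(movie, f0_quantile = 0.05) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$data)
  x <- movie$data
  dim(x) <- c(d[1] * d[2], d[3])
  f0 <- pixelwise_quantile(x, f0_quantile)
  if (any(f0 <= 0))
    stop("per-pixel baseline F0 is not positive everywhere; ",
         "add a positive intensity offset to the stack before normalizing")
  y <- (x - f0) / f0
  dim(y) <- d
  structure(list(dff = y, f0 = matrix(f0, d[1], d[2]),
                 frame_rate = movie$frame_rate, um_per_px = movie$um_per_px),
            class = "dff_movie")
}

#' @export
print.dff_movie <- function(x, ...) {
  d <- dim(x$dff)
  cat(sprintf("<dff_movie> %d x %d px, %d frames @ %g Hz\n",
              d[1], d[2], d[3], x$frame_rate))
  invisible(x)
}

# Row-wise quantile of a matrix (rows = pixels, cols = frames), type 7.
pixelwise_quantile <- function(x, p) {
  n <- ncol(x)
  h <- (n - 1) * p + 1
  k <- floor(h)
  g <- h - k
  xs <- apply(x, 1L, sort.int, method = "quick")  # n x npix
  if (g == 0) xs[k, ] else (1 - g) * xs[k, ] + g * xs[k + 1L, ]
}

#' Correct an image stack for photobleaching
#'
#' Fits a single exponential `m(t) = a + b * exp(-t / tau)` to the frame-mean
#' intensity trace and subtracts the decaying component from every pixel of
#' frame `t`, anchored so the corrected frame mean stays at its fitted
#' initial value `m(0) = a + b` (each frame receives `-(m(t) - m(0))`). This
#' keeps baseline fluorescence, and therefore later dF/F0 amplitudes, on the
#' pre-bleach scale. If the trace does not decay (fit failure or `b <= 0`)
#' the stack is returned unchanged with a warning.
#'
#' @param movie a [movie_stack] with at least 20 frames.
#' @return a [movie_stack]; the fitted `a`, `b`, `tau` are attached as the
#'   `"bleach_fit"` attribute (`NULL` when no correction was applied).
#' @export
bleach_correct <- function(movie) {
  stopifnot(inherits(movie, "movie_stack"))
  nt <- n_frames(movie)
  if (nt < 20) stop("bleach correction needs at least 20 frames")
  t <- frame_times(movie)
  m <- apply(movie$data, 3L, mean)
  # robust Levenberg-Marquardt fit; self-starting asymptotic fit as fallback
  fit <- tryCatch(
    minpack.lm::nlsLM(m ~ a + b * exp(-t / tau),
                      start = list(a = m[nt], b = m[1] - m[nt],
                                   tau = max(t) / 2),
                      lower = c(-Inf, -Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) tryCatch(nls(m ~ SSasymp(t, Asym, R0, lrc)),
                                 error = function(e2) NULL))
  if (is.null(fit)) {
    warning("photobleaching fit failed; returning stack unchanged")
    return(structure(movie, bleach_fit = NULL))
  }
  cf <- coef(fit)
  if ("lrc" %in% names(cf)) {
    a <- unname(cf["Asym"])
    b <- unname(cf["R0"] - cf["Asym"])
    tau <- unname(exp(-cf["lrc"]))
  } else {
    a <- unname(cf["a"]); b <- unname(cf["b"]); tau <- unname(cf["tau"])
  }
  if (!is.finite(b) || b <= 0) {
    warning("frame-mean trace does not decay; returning stack unchanged")
    return(structure(movie, bleach_fit = NULL))
  }
  decay <- b * exp(-t / tau) - b      # m(t) - m(0); zero at t = 0
  out <- movie
  out$data <- movie$data - rep(decay, each = prod(dim(movie$data)[1:2]))
  structure(out, bleach_fit = c(a = a, b = b, tau = tau))
}

#' Difference movie
#'
#' Frame `k` of the output is `frame(k + L) - frame(k)` where `L` is the lag
#' in frames (`round(lag * frame_rate)`), producing an index of slow
#' intensity (transmittance) change over time. The output has `T - L` frames.
#'
#' @param movie a [movie_stack].
#' @param lag lag in seconds (default 5).
#' @return a [movie_stack] of differences.
#' @export
difference_movie <- function(movie, lag = 5) {
  stopifnot(inherits(movie, "movie_stack"))
  L <- round(lag * movie$frame_rate)
  if (L < 1) stop("lag must span at least one frame")
  nt <- n_frames(movie)
  if (nt <= L) stop("movie is shorter than the requested lag")
  d <- movie$data[, , (L + 1):nt, drop = FALSE] -
    movie$data[, , 1:(nt - L), drop = FALSE]
  movie_stack(d, movie$frame_rate, movie$um_per_px)
}

#' Threshold an image stack at k SDs above the mean
#'
#' By default the mean and SD are computed globally over all pixels and
#' frames; with `per_pixel = TRUE` they are computed per pixel over time.
#'
#' @param x a [movie_stack] or [dff_movie].
#' @param threshold_k SD multiplier (default 3).
#' @param per_pixel use per-pixel temporal statistics instead of global ones.
#' @return a logical array of the same shape (`TRUE` = suprathreshold).
#'   Zero-variance input yields an all-`FALSE` mask.
#' @export
threshold_mask <- function(x, threshold_k = 3, per_pixel = FALSE) {
  v <- if (inherits(x, "dff_movie")) x$dff else x$data
  d <- dim(v)
  if (per_pixel) {
    dim(v) <- c(d[1] * d[2], d[3])
    mu <- rowMeans(v)
    s <- sqrt(rowMeans(v * v) - mu^2) * sqrt(d[3] / (d[3] - 1))
    m <- v > mu + threshold_k * s
    dim(m) <- d
    return(m)
  }
  mu <- mean(v)
  s <- sd(as.vector(v))
  if (!is.finite(s) || s == 0) return(array(FALSE, d))
  v > mu + threshold_k * s
}

# Normalized Gaussian smoothing of a matrix; sigma <= 0 is the identity.
# Frames smaller than the kernel are zero-padded before filtering.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  size <- 2L * r + 1L
  br <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
  br <- br / sum(br)
  if (nrow(m) < size || ncol(m) < size) {
    pad <- matrix(0, nrow(m) + 2 * r, ncol(m) + 2 * r)
    pad[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m))] <- m
    sm <- EBImage::filter2(pad, br, boundary = 0)
    return(sm[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m))])
  }
  EBImage::filter2(m, br, boundary = 0)
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so
# labels touching diagonally are merged afterwards.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]    # down-right diagonal
  c1 <- lab[-1, -nc]; d1 <- lab[-nr, -1]  # up-right diagonal
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c1), as.vector(d1)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (!nrow(pairs)) return(lab)
  # union-find over label ids
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ri <- find(pairs[k, 1]); rj <- find(pairs[k, 2])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Measure region areas in a binary frame
#'
#' The binary mask is Gaussian-smoothed (border detection), re-binarized at
#' 0.5, labelled with 8-connectivity, and each component's area is its pixel
#' count times `um_per_px^2`.
#'
#' @param mask_frame logical or 0/1 matrix.
#' @param gauss_sigma smoothing sigma in pixels (default 2); `0` disables
#'   smoothing.
#' @param um_per_px pixel size in micrometres.
#' @return a data frame with one row per region: `label`, `n_px`, `area_um2`,
#'   `centroid_row`, `centroid_col`. Empty masks give zero rows.
#' @export
region_areas <- function(mask_frame, gauss_sigma = 2.0, um_per_px = 1) {
  m <- gaussian_smooth(mask_frame * 1, gauss_sigma) >= 0.5
  lab <- label_components8(m)
  n <- max(lab)
  if (n == 0)
    return(data.frame(label = integer(), n_px = integer(),
                      area_um2 = numeric(), centroid_row = numeric(),
                      centroid_col = numeric()))
  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  n_px <- tabulate(lv, n)
  data.frame(label = seq_len(n), n_px = n_px,
             area_um2 = n_px * um_per_px^2,
             centroid_row = as.vector(tapply(idx[, 1], lv, mean)),
             centroid_col = as.vector(tapply(idx[, 2], lv, mean)))
}

#' Detect peaks in a 1-D trace above a fixed threshold
#'
#' Local maxima above `threshold` are found (plateaus count once, at their
#' centre sample) and a minimum separation is enforced greedily, keeping the
#' larger of two conflicting peaks.
#'
#' @param x numeric trace.
#' @param threshold fixed value threshold; only samples strictly above it can
#'   be peaks.
#' @param min_sep minimum peak separation in seconds (default 0).
#' @param rate_hz sampling rate of `x` in Hz (default 1, i.e. `x` indexed in
#'   seconds).
#' @return a data frame with `index`, `time`, `value`, sorted by time.
#' @export
find_peaks_threshold <- function(x, threshold, min_sep = 0, rate_hz = 1) {
  n <- length(x)
  if (n < 3) return(data.frame(index = integer(), time = numeric(),
                               value = numeric()))
  # collapse plateaus to their centre, then test strict neighbours
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  centres <- floor((starts + ends) / 2)
  vals <- r$values
  k <- length(vals)
  is_pk <- logical(k)
  if (k >= 3) {
    inner <- 2:(k - 1)
    is_pk[inner] <- vals[inner] > vals[inner - 1] & vals[inner] > vals[inner + 1]
  }
  cand <- centres[is_pk & vals > threshold]
  if (!length(cand)) return(data.frame(index = integer(), time = numeric(),
                                       value = numeric()))
  if (min_sep > 0 && length(cand) > 1) {
    sep_samp <- min_sep * rate_hz
    ord <- cand[order(-x[cand], cand)]
    keep <- integer(0)
    for (i in ord)
      if (!length(keep) || all(abs(keep - i) >= sep_samp)) keep <- c(keep, i)
    cand <- sort(keep)
  }
  data.frame(index = cand, time = (cand - 1) / rate_hz, value = x[cand])
}
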