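#' Detect widefield events in the inferior colliculus
#'
#' Per lobe, the mean dF/F trace (in percent) is extracted from the lobe ROI
#' and peaks above a fixed 2 percent threshold are detected. Each event's
#' amplitude is its baseline-subtracted peak (local baseline: median of the
#' trace over the `baseline_s` seconds preceding event onset, the last upward
#' threshold crossing before the peak), and `half_width` is the full width at
#' half of (peak - baseline), linearly interpolated.
#'
#' @param dffm a [dff_movie].
#' @param lobe_rois a [roi_set] with ROIs named `left` and `right`.
#' @param threshold_pct fixed detection threshold in percent dF/F (default 2).
#' @param min_sep minimum peak separation in seconds (default 1).
#' @param baseline_s local-baseline window in seconds (default 5).
#' @return a data frame of events: `time`, `lobe`, `amplitude_pct`,
#'   `half_width`, `frame`.
#' @export
detect_ic_events <- function(dffm, lobe_rois, threshold_pct = 2,
                             min_sep = 1, baseline_s = 5) {
  stopifnot(inherits(dffm, "dff_movie"), inherits(lobe_rois, "roi_set"))
  if (!all(c("left", "right") %in% names(lobe_rois)))
    stop("lobe_rois must contain ROIs named 'left' and 'right'")
  fps <- dffm$frame_rate
  out <- list()
  for (lobe in c("left", "right")) {
    tr <- 100 * roi_trace(dffm, lobe_rois[[lobe]])
    pk <- find_peaks_threshold(tr, threshold_pct, min_sep = min_sep,
                               rate_hz = fps)
    if (!nrow(pk)) next
    amp <- hw <- numeric(nrow(pk))
    for (i in seq_len(nrow(pk))) {
      k <- pk$index[i]
      # onset: last upward crossing of the threshold before the peak
      pre <- which(tr[seq_len(k - 1)] < threshold_pct)
      onset <- if (length(pre)) max(pre) + 1L else 1L
      bl_lo <- max(1L, onset - round(baseline_s * fps))
      bl <- median(tr[bl_lo:max(bl_lo, onset - 1L)])
      amp[i] <- tr[k] - bl
      half <- bl + amp[i] / 2
      hw[i] <- fwhm_at(tr, k, half) / fps
    }
    out[[lobe]] <- data.frame(time = pk$time, lobe = lobe,
                              amplitude_pct = amp, half_width = hw,
                              frame = pk$index)
  }
  if (!length(out))
    return(data.frame(time = numeric(), lobe = character(),
                      amplitude_pct = numeric(), half_width = numeric(),
                      frame = integer()))
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$time, res$lobe), ]
}

# full width (in samples) of trace around peak k at level `half`
fwhm_at <- function(tr, k, half) {
  n <- length(tr)
  i <- k
  while (i > 1 && tr[i - 1] > half) i <- i - 1
  left <- if (i == 1 || tr[i - 1] == tr[i]) i
  else i - (half - tr[i]) / (tr[i - 1] - tr[i]) * 1  # interpolate
  j <- k
  while (j < n && tr[j + 1] > half) j <- j + 1
  right <- if (j == n || tr[j + 1] == tr[j]) j
  else j + (tr[j] - half) / (tr[j] - tr[j + 1]) * 1
  right - left
}

#' Pair simultaneous events across the two IC lobes
#'
#' Greedy nearest-in-time pairing of left/right events within `window`
#' seconds (ties resolved toward the earlier event); each event is used at
#' most once. For each pair the bilateral amplitude ratio (weak/strong, in
#' `(0, 1]`) and the dominant lobe are reported.
#'
#' @param events data frame from [detect_ic_events].
#' @param window pairing half-window in seconds (default 0.5).
#' @return a list with `pairs` (data frame: `time`, `strong_amp`, `weak_amp`,
#'   `ratio`, `dominant_lobe`) and `unmatched` (the unpaired events).
#' @export
match_bilateral <- function(events, window = 0.5) {
  left <- events[events$lobe == "left", , drop = FALSE]
  right <- events[events$lobe == "right", , drop = FALSE]
  pairs <- data.frame(time = numeric(), strong_amp = numeric(),
                      weak_amp = numeric(), ratio = numeric(),
                      dominant_lobe = character())
  if (nrow(left) && nrow(right)) {
    dt <- abs(outer(left$time, right$time, "-"))
    cand <- which(dt <= window, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(dt[cand], pmin(left$time[cand[, 1]],
                                  right$time[cand[, 2]]))
      cand <- cand[ord, , drop = FALSE]
      used_l <- logical(nrow(left)); used_r <- logical(nrow(right))
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (used_l[i] || used_r[j]) next
        used_l[i] <- TRUE; used_r[j] <- TRUE
        a_l <- left$amplitude_pct[i]; a_r <- right$amplitude_pct[j]
        strong <- max(a_l, a_r); weak <- min(a_l, a_r)
        pairs <- rbind(pairs, data.frame(
          time = min(left$time[i], right$time[j]),
          strong_amp = strong, weak_amp = weak, ratio = weak / strong,
          dominant_lobe = if (a_l >= a_r) "left" else "right"))
      }
      unmatched <- rbind(left[!used_l, , drop = FALSE],
                         right[!used_r, , drop = FALSE])
      return(list(pairs = pairs[order(pairs$time), , drop = FALSE],
                  unmatched = unmatched))
    }
  }
  list(pairs = pairs, unmatched = events)
}

#' Drop globally spreading events
#'
#' Events whose suprathreshold coverage of their lobe ROI at the peak frame
#' exceeds `coverage_frac` (strictly) are removed; such events reflect
#' activity invading the whole IC surface rather than spatially confined
#' peripheral drive.
#'
#' @param events data frame from [detect_ic_events].
#' @param dffm the [dff_movie] the events were detected in.
#' @param lobe_rois the lobe [roi_set].
#' @param coverage_frac coverage threshold in `(0, 1]` (default 0.8).
#' @param threshold_pct pixel activity threshold in percent dF/F (default 2).
#' @return the filtered events data frame, with a `coverage` column added.
#' @export
exclude_global_events <- function(events, dffm, lobe_rois,
                                  coverage_frac = 0.8, threshold_pct = 2) {
  if (coverage_frac <= 0 || coverage_frac > 1)
    stop("`coverage_frac` must lie in (0, 1]")
  if (!nrow(events)) { events$coverage <- numeric(0); return(events) }
  d <- dim(dffm$dff)
  masks <- lapply(lobe_rois, roi_mask, dims = d[1:2])
  cov <- vapply(seq_len(nrow(events)), function(i) {
    m <- masks[[events$lobe[i]]]
    fr <- dffm$dff[, , events$frame[i]]
    mean(fr[m] * 100 > threshold_pct)
  }, numeric(1))
  events$coverage <- cov
  events[cov <= coverage_frac, , drop = FALSE]
}

#' Tonotopic line scan
#'
#' Samples the rotated `length_px` x `width_px` rectangle (bilinear
#' interpolation) in every frame and averages across the width, producing a
#' position x time matrix of percent dF/F. Position runs from the lateral
#' edge (the geometry anchor) in micrometres.
#'
#' @param dffm a [dff_movie].
#' @param geom a [scan_geometry] (canonically 125 x 50 px at +/-55 degrees).
#' @return an object of class `tonotopic_scan`: `values` (length_px x frames,
#'   percent dF/F), `position_um`, `times`, `geom`.
#' @export
tonotopic_linescan <- function(dffm, geom) {
  stopifnot(inherits(dffm, "dff_movie"), inherits(geom, "scan_geometry"))
  d <- dim(dffm$dff)
  L <- geom$length_px; W <- geom$width_px
  off_w <- seq_len(W) - (W + 1) / 2
  # sample coordinates (x = col, y = row) for all L*W points
  ax <- rep(seq_len(L) - 1, times = W)
  aw <- rep(off_w, each = L)
  px <- geom$anchor[1] + ax * geom$u[1] + aw * geom$v[1]
  py <- geom$anchor[2] + ax * geom$u[2] + aw * geom$v[2]
  if (any(px < 1) || any(px > d[2]) || any(py < 1) || any(py > d[1]))
    stop("scan rectangle extends outside the frame")
  x0 <- floor(px); y0 <- floor(py)
  x0 <- pmin(x0, d[2] - 1L); y0 <- pmin(y0, d[1] - 1L)
  fx <- px - x0; fy <- py - y0
  i00 <- (x0 - 1) * d[1] + y0          # linear index of (y0, x0)
  i10 <- i00 + 1L                      # (y0+1, x0)
  i01 <- i00 + d[1]                    # (y0, x0+1)
  i11 <- i01 + 1L
  w00 <- (1 - fx) * (1 - fy); w10 <- (1 - fx) * fy
  w01 <- fx * (1 - fy); w11 <- fx * fy
  npx <- d[1] * d[2]
  vals <- matrix(0, L, d[3])
  for (k in seq_len(d[3])) {
    fr <- dffm$dff[, , k]
    samp <- w00 * fr[i00] + w10 * fr[i10] + w01 * fr[i01] + w11 * fr[i11]
    vals[, k] <- rowMeans(matrix(samp, L, W))
  }
  structure(list(values = 100 * vals,
                 position_um = (seq_len(L) - 1) * dffm$um_per_px,
                 times = (seq_len(d[3]) - 1) / dffm$frame_rate,
                 geom = geom),
            class = "tonotopic_scan")
}

#' Detect band peaks in a tonotopic line scan
#'
#' Regional maxima of the position x time scan (strictly greater than all 8
#' neighbours) above a constant threshold.
#'
#' @param scan a `tonotopic_scan` from [tonotopic_linescan].
#' @param threshold_pct constant threshold in percent dF/F (default 3).
#' @return a data frame: `position_um`, `time`, `amplitude_pct`, `pos_idx`,
#'   `frame`.
#' @export
detect_band_peaks <- function(scan, threshold_pct = 3) {
  stopifnot(inherits(scan, "tonotopic_scan"))
  v <- scan$values
  nr <- nrow(v); nc <- ncol(v)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- v
  is_max <- v > threshold_pct
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & (v > pad[2:(nr + 1) + di, 2:(nc + 1) + dj])
  }
  idx <- which(is_max, arr.ind = TRUE)
  data.frame(position_um = scan$position_um[idx[, 1]],
             time = scan$times[idx[, 2]],
             amplitude_pct = v[idx],
             pos_idx = idx[, 1], frame = idx[, 2])[order(scan$times[idx[, 2]]), ]
}

#' Spatial histogram of band events along the tonotopic axis
#'
#' Counts band peaks in fixed-width bins along the axis and splits them into
#' lateral (`position < split_um`) and medial (`position >= split_um`)
#' frequencies. An optional exclusion zone around the single-band locus
#' removes bifurcation-edge events before counting.
#'
#' @param peaks data frame from [detect_band_peaks].
#' @param duration_min recording duration in minutes (for frequencies).
#' @param split_um medial/lateral split position in micrometres; canonically
#'   the midpoint between the lateral edge and the single-band locus.
#' @param bin_um bin width (default 25).
#' @param axis_max_um axis extent (default: last bin edge covering the data).
#' @param exclusion_center_um,exclusion_halfwidth_um optional exclusion zone
#'   around the single-band locus (default half-width 50).
#' @return a list: `histogram` (data frame `lower`, `upper`, `count`),
#'   `n_lateral`, `n_medial`, `lateral_freq_per_min`, `medial_freq_per_min`,
#'   `n_excluded`.
#' @export
spatial_event_histogram <- function(peaks, duration_min, split_um,
                                    bin_um = 25, axis_max_um = NULL,
                                    exclusion_center_um = NULL,
                                    exclusion_halfwidth_um = 50) {
  pos <- peaks$position_um
  n_exc <- 0L
  if (!is.null(exclusion_center_um)) {
    drop <- abs(pos - exclusion_center_um) <= exclusion_halfwidth_um
    n_exc <- sum(drop)
    pos <- pos[!drop]
  }
  if (is.null(axis_max_um))
    axis_max_um <- bin_um * max(1, ceiling(max(c(pos, split_um)) / bin_um))
  if (split_um <= 0 || split_um > axis_max_um)
    stop("`split_um` must lie inside the axis range")
  edges <- seq(0, axis_max_um, by = bin_um)
  if (edges[length(edges)] < axis_max_um) edges <- c(edges, axis_max_um)
  nb <- length(edges) - 1L
  cnt <- if (length(pos))
    tabulate(pmin(findInterval(pos, edges, rightmost.closed = TRUE), nb), nb)
  else integer(nb)
  n_lat <- sum(pos < split_um)
  n_med <- sum(pos >= split_um)
  list(histogram = data.frame(lower = edges[-(nb + 1)], upper = edges[-1],
                              count = cnt),
       n_lateral = n_lat, n_medial = n_med,
       lateral_freq_per_min = n_lat / duration_min,
       medial_freq_per_min = n_med / duration_min,
       n_excluded = n_exc)
}

#' Detect retinal waves in the superior colliculus
#'
#' Per lobe: crop the ROI (canonically 200 x 150 px), block-mean downsample
#' by `down_factor`, normalize to dF/F0 (5th-percentile F0), subtract the
#' per-frame all-pixel mean to remove whole-sample fluctuations, mark a pixel
#' active when it exceeds its temporal mean + `active_k` SD, and call a wave
#' any maximal run of frames with more than `min_active` simultaneously
#' active pixels lasting strictly longer than `min_duration` seconds.
#'
#' @param movie a [movie_stack].
#' @param sc_rois a [roi_set] of rectangular lobe ROIs, each at least
#'   `min_roi_px` in size.
#' @param down_factor spatial downsampling factor (default 5).
#' @param active_k activity threshold in SDs (default 3).
#' @param min_active minimum simultaneously active pixels, strict (default 5).
#' @param min_duration minimum wave duration in seconds, strict (default 1).
#' @param min_roi_px required ROI size `c(width, height)` in px (default
#'   200 x 150).
#' @return a list with `waves` (data frame: `lobe`, `start`, `duration`),
#'   `frequency_per_min`, `mean_duration`, and per-lobe active-pixel-count
#'   traces in `active_counts`.
#' @export
detect_retinal_waves <- function(movie, sc_rois, down_factor = 5,
                                 active_k = 3, min_active = 5,
                                 min_duration = 1,
                                 min_roi_px = c(200, 150)) {
  stopifnot(inherits(movie, "movie_stack"), inherits(sc_rois, "roi_set"))
  fps <- movie$frame_rate
  nt <- n_frames(movie)
  waves <- list(); counts <- list()
  for (nm in names(sc_rois)) {
    roi <- sc_rois[[nm]]
    if (roi$shape != "rect") stop("SC lobe ROIs must be rectangles")
    if (roi$w < min_roi_px[1] || roi$h < min_roi_px[2])
      stop(sprintf("ROI '%s' is smaller than the required %d x %d px",
                   nm, min_roi_px[1], min_roi_px[2]))
    rows <- roi$y:(roi$y + roi$h - 1)
    cols <- roi$x:(roi$x + roi$w - 1)
    sub <- movie$data[rows, cols, , drop = FALSE]
    ds <- block_mean_downsample(sub, down_factor)
    dd <- dim(ds)
    x <- ds
    dim(x) <- c(dd[1] * dd[2], dd[3])
    f0 <- pixelwise_quantile(x, 0.05)
    if (any(f0 <= 0))
      stop("non-positive F0 in SC ROI; offset the stack before analysis")
    x <- (x - f0) / f0
    x <- sweep(x, 2L, colMeans(x))          # per-frame mean subtraction
    mu <- rowMeans(x)
    s <- sqrt(pmax(rowMeans(x * x) - mu^2, 0) * dd[3] / (dd[3] - 1))
    active <- x > mu + active_k * s
    cnt <- colSums(active)
    counts[[nm]] <- cnt
    over <- cnt > min_active
    r <- rle(over)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      dur <- r$lengths[i] / fps
      if (dur > min_duration)
        waves[[length(waves) + 1L]] <-
          data.frame(lobe = nm, start = (starts[i] - 1) / fps, duration = dur)
    }
  }
  wv <- if (length(waves)) do.call(rbind, waves)
  else data.frame(lobe = character(), start = numeric(), duration = numeric())
  wv <- wv[order(wv$start), , drop = FALSE]
  rownames(wv) <- NULL
  list(waves = wv,
       frequency_per_min = nrow(wv) / (nt / fps / 60) / max(1, length(sc_rois)),
       mean_duration = if (nrow(wv)) mean(wv$duration) else NA_real_,
       active_counts = counts)
}

# block-mean downsample a [rows, cols, frames] array by integer factor f
block_mean_downsample <- function(a, f) {
  d <- dim(a)
  nr <- floor(d[1] / f); nc <- floor(d[2] / f)
  a <- a[seq_len(nr * f), seq_len(nc * f), , drop = FALSE]
  dim(a) <- c(f, nr, f * nc * d[3])
  a <- colMeans(a)                          # nr x (f*nc*d3)
  dim(a) <- c(nr, f, nc * d[3])
  a <- aperm(a, c(2, 1, 3))
  a <- colMeans(a)                          # nr x nc*d3
  dim(a) <- c(nr, nc, d[3])
  a
}
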