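#' Crenation frequency and area from a transmitted-light movie
#'
#' Pipeline: difference movie at `cfg$diff_lag`, global threshold at
#' `cfg$threshold_k` SDs above the mean, per-frame count of suprathreshold
#' pixels taken as the whole-field trace, peaks in that trace (robust
#' threshold: median + 3 x 1.4826 MAD of the count trace, minimum separation
#' `cfg$min_peak_sep`), and per-event area from [region_areas] on the
#' thresholded difference frame at each peak (largest region reported).
#'
#' @param movie a [movie_stack] (transmitted light).
#' @param cfg a [detection_config].
#' @return a list with `events` (data frame: `time` s, `frame` index into the
#'   difference movie, `n_px` suprathreshold pixels, `area_um2`),
#'   `frequency_per_min`, and the per-frame `count_trace`.
#' @export
crenation_stats <- function(movie, cfg = detection_config()) {
  stopifnot(inherits(movie, "movie_stack"))
  if (movie_duration(movie) < 2 * cfg$diff_lag)
    stop("movie must be at least twice the difference lag")
  dm <- difference_movie(movie, cfg$diff_lag)
  mask <- threshold_mask(dm, cfg$threshold_k)
  counts <- apply(mask, 3L, sum)
  thr <- median(counts) + 3 * mad(counts)
  pk <- find_peaks_threshold(counts, thr, min_sep = cfg$min_peak_sep,
                             rate_hz = movie$frame_rate)
  area <- vapply(pk$index, function(k) {
    reg <- region_areas(mask[, , k], cfg$gauss_sigma, movie$um_per_px)
    if (nrow(reg)) max(reg$area_um2) else 0
  }, numeric(1))
  events <- data.frame(time = pk$time, frame = pk$index,
                       n_px = counts[pk$index], area_um2 = area)
  list(events = events,
       frequency_per_min = nrow(events) / (movie_duration(movie) / 60),
       count_trace = counts)
}

#' Per-compartment Ca2+ transient statistics
#'
#' For each ROI the mean dF/F trace is extracted, peaks are detected above
#' the trace mean + 3 SD (fixed per ROI) with minimum separation
#' `cfg$min_peak_sep`, and per-event area is measured by thresholding the
#' peak frame per pixel (temporal mean + 3 SD) and running [region_areas]
#' (largest region intersecting the ROI).
#'
#' @param dffm a [dff_movie].
#' @param rois a [roi_set] (compartment ROIs: ISC, IHC, SGN, ...).
#' @param cfg a [detection_config].
#' @return a list with `events` (data frame: `roi`, `compartment`, `time`,
#'   `amplitude` fractional dF/F, `area_um2`) and `summary` (per-ROI
#'   `n_events` and `freq_per_min`).
#' @export
calcium_event_stats <- function(dffm, rois, cfg = detection_config()) {
  stopifnot(inherits(dffm, "dff_movie"), inherits(rois, "roi_set"))
  d <- dim(dffm$dff)
  dur_min <- d[3] / dffm$frame_rate / 60
  pp_mask <- NULL  # lazily computed per-pixel suprathreshold mask
  events <- list()
  summ <- list()
  for (nm in names(rois)) {
    roi <- rois[[nm]]
    tr <- roi_trace(dffm, roi)
    thr <- mean(tr) + cfg$threshold_k * sd(tr)
    pk <- find_peaks_threshold(tr, thr, min_sep = cfg$min_peak_sep,
                               rate_hz = dffm$frame_rate)
    area <- rep(NA_real_, nrow(pk))
    if (nrow(pk)) {
      if (is.null(pp_mask))
        pp_mask <- threshold_mask(dffm, cfg$threshold_k, per_pixel = TRUE)
      rmask <- roi_mask(roi, d[1:2])
      for (i in seq_len(nrow(pk))) {
        reg <- region_areas(pp_mask[, , pk$index[i]] & rmask,
                            cfg$gauss_sigma, dffm$um_per_px)
        area[i] <- if (nrow(reg)) max(reg$area_um2) else 0
      }
      events[[nm]] <- data.frame(roi = nm,
                                 compartment = roi$compartment %||% nm,
                                 time = pk$time, amplitude = pk$value,
                                 area_um2 = area)
    }
    summ[[nm]] <- data.frame(roi = nm, n_events = nrow(pk),
                             freq_per_min = nrow(pk) / dur_min)
  }
  list(events = if (length(events)) do.call(rbind, c(events,
                                                     make.row.names = FALSE))
       else data.frame(roi = character(), compartment = character(),
                       time = numeric(), amplitude = numeric(),
                       area_um2 = numeric()),
       summary = do.call(rbind, c(summ, make.row.names = FALSE)))
}

#' Pairwise IHC correlation analysis
#'
#' Pearson correlation between the dF/F traces of every hair-cell pair, the
#' per-cell mean over its four nearest neighbours (centroid Euclidean
#' distance, ties broken by ROI order; edge cells use all available
#' neighbours), and the group mean of those per-cell means.
#'
#' @param dffm a [dff_movie].
#' @param ihc_rois a [roi_set] of at least 5 individually indexed IHC ROIs.
#' @param n_neighbors neighbours per cell (default 4).
#' @return a list of class `correlation_result`: `matrix` (symmetric, unit
#'   diagonal; `NA` for zero-variance traces), `mean_nearest4` (named per
#'   cell), `group_mean`, `excluded` (names of zero-variance cells).
#' @export
ihc_correlation <- function(dffm, ihc_rois, n_neighbors = 4) {
  stopifnot(inherits(dffm, "dff_movie"), inherits(ihc_rois, "roi_set"))
  if (length(ihc_rois) < 5) stop("at least 5 IHC ROIs are required")
  tr <- vapply(ihc_rois, function(r) roi_trace(dffm, r),
               numeric(dim(dffm$dff)[3]))
  sds <- apply(tr, 2, sd)
  excluded <- colnames(tr)[sds == 0]
  cm <- suppressWarnings(cor(tr))
  cm[sds == 0, ] <- NA; cm[, sds == 0] <- NA
  diag(cm) <- 1
  ctr <- t(vapply(ihc_rois, roi_centroid, numeric(2)))
  n <- nrow(ctr)
  mn4 <- setNames(rep(NA_real_, n), names(ihc_rois))
  for (i in seq_len(n)) {
    dd <- sqrt((ctr[, 1] - ctr[i, 1])^2 + (ctr[, 2] - ctr[i, 2])^2)
    ord <- order(dd, seq_len(n))           # ties broken by ROI index
    nb <- setdiff(ord, i)[seq_len(min(n_neighbors, n - 1))]
    vals <- cm[i, nb]
    if (any(!is.na(vals))) mn4[i] <- mean(vals, na.rm = TRUE)
  }
  structure(list(matrix = cm, mean_nearest4 = mn4,
                 group_mean = mean(mn4, na.rm = TRUE), excluded = excluded),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %d cells, group mean nearest-neighbour r = %.3f\n",
              nrow(x$matrix), x$group_mean))
  invisible(x)
}
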