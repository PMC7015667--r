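#' Line-scan / band geometry for one IC lobe
#'
#' The rectangle used both by the generator (to place tonotopic bands) and by
#' [tonotopic_linescan]: `length_px` samples along the scan axis starting at
#' `anchor` (the lateral edge), `width_px` across, rotated by `angle_deg`
#' (degrees, counter-clockwise in x = column / y = row coordinates).
#'
#' @param anchor `c(x, y)` pixel position of the lateral end of the axis.
#' @param angle_deg rotation of the axis direction in degrees (the canonical
#'   placements are +55 and -55 for the two lobes).
#' @param length_px samples along the axis (default 125).
#' @param width_px width across the axis (default 50).
#' @return a list of class `scan_geometry`.
#' @export
scan_geometry <- function(anchor, angle_deg, length_px = 125, width_px = 50) {
  th <- angle_deg * pi / 180
  structure(list(anchor = anchor, angle_deg = angle_deg,
                 length_px = length_px, width_px = width_px,
                 u = c(cos(th), sin(th)),          # axis direction (x, y)
                 v = c(-sin(th), cos(th))),        # across-axis direction
            class = "scan_geometry")
}

#' Specification for a synthetic widefield movie
#'
#' Shared container for all movie modes (`IC`, `SC`, `cochlea`,
#' `crenation`). The event schedule is a data frame whose columns depend on
#' the mode; see [gen_widefield_movie]. Events are injected multiplicatively
#' (`F = baseline * (1 + S)`), photobleaching as a multiplicative single
#' exponential, and Gaussian noise additively.
#'
#' @param shape `c(rows, cols, frames)`.
#' @param frame_rate frames per second.
#' @param um_per_px pixel size in micrometres.
#' @param event_schedule data frame of scheduled events (may have zero rows).
#' @param baseline baseline intensity (default 1000).
#' @param bleach_tau photobleaching time constant in seconds; 0 disables.
#' @param noise_sd additive Gaussian noise SD in intensity units.
#' @param bilateral_ratio weak/strong amplitude ratio in `[0, 1]` for paired
#'   IC events (0 disables automatic pairing).
#' @param geometry mode-specific geometry list (see [gen_widefield_movie]).
#' @param seed integer seed.
#' @return an object of class `movie_gen_spec`.
#' @export
movie_gen_spec <- function(shape, frame_rate, um_per_px,
                           event_schedule = NULL, baseline = 1000,
                           bleach_tau = 0, noise_sd = 0,
                           bilateral_ratio = 0, geometry = list(),
                           seed = NULL) {
  stopifnot(length(shape) == 3, all(shape >= 1))
  stop_if_not_scalar_pos(frame_rate, "frame_rate")
  stop_if_not_scalar_pos(um_per_px, "um_per_px")
  if (noise_sd < 0 || bleach_tau < 0) stop("noise_sd and bleach_tau must be >= 0")
  if (bilateral_ratio < 0 || bilateral_ratio > 1)
    stop("`bilateral_ratio` must lie in [0, 1]")
  if (!is.null(event_schedule) && nrow(event_schedule)) {
    if (any(event_schedule$amplitude <= 0)) stop("event amplitudes must be > 0")
    dur <- shape[3] / frame_rate
    if (any(event_schedule$time < 0) || any(event_schedule$time >= dur))
      stop("event schedule is inconsistent with the movie duration")
  }
  structure(list(shape = shape, frame_rate = frame_rate,
                 um_per_px = um_per_px, event_schedule = event_schedule,
                 baseline = baseline, bleach_tau = bleach_tau,
                 noise_sd = noise_sd, bilateral_ratio = bilateral_ratio,
                 geometry = geometry, seed = seed),
            class = "movie_gen_spec")
}

# temporal alpha kernel, peak 1 at lag tau
alpha_kernel <- function(t_rel, tau) {
  k <- numeric(length(t_rel))
  p <- t_rel >= 0
  k[p] <- (t_rel[p] / tau) * exp(1 - t_rel[p] / tau)
  k
}

# Gaussian band field over a frame for one lobe geometry:
# exp(-(d_axis - pos)^2 / 2 s_ax^2) * exp(-d_perp^2 / 2 s_pp^2), distances um.
band_field <- function(dims, geom, position_um, width_um, um_per_px) {
  nr <- dims[1]; nc <- dims[2]
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc) - geom$anchor[1]
  ys <- matrix(rep(seq_len(nr), nc), nr, nc) - geom$anchor[2]
  d_ax <- (xs * geom$u[1] + ys * geom$u[2]) * um_per_px
  d_pp <- (xs * geom$v[1] + ys * geom$v[2]) * um_per_px
  s_ax <- width_um / 2.355                       # width_um is the band FWHM
  s_pp <- geom$width_px * um_per_px              # broad across the axis
  f <- exp(-(d_ax - position_um)^2 / (2 * s_ax^2)) *
       exp(-d_pp^2 / (2 * s_pp^2))
  f[d_ax < -2 * s_ax | d_ax > (geom$length_px * um_per_px + 2 * s_ax)] <- 0
  f
}

add_event_frames <- function(S, field, kernel, frames) {
  d <- dim(S)
  inc <- as.vector(field) %o% kernel
  S[, , frames] <- S[, , frames] + array(inc, c(d[1], d[2], length(frames)))
  S
}

#' Generate a synthetic widefield movie with ground truth
#'
#' Modes and their schedule columns / geometry:
#' \describe{
#'   \item{`IC`}{Stationary tonotopic bands on two lobes. Schedule columns:
#'     `time`, `lobe` (`"left"`/`"right"`, the dominant lobe), `amplitude`
#'     (peak fractional dF/F at the band centre), `position_um` (along the
#'     scan axis from the lateral edge), `width_um` (band FWHM), `duration`
#'     (s). Geometry: `list(left =, right = scan_geometry(...))`. When
#'     `bilateral_ratio > 0` every event gets a contralateral partner of
#'     amplitude `amplitude * bilateral_ratio` at the same time and
#'     position.}
#'   \item{`SC`}{Propagating retinal waves. Schedule columns: `time`, `lobe`,
#'     `duration` (s), `n_px` (downsampled-pixel footprint), `amplitude`.
#'     Geometry: `list(<lobe> = roi_rect(...), down_factor = 5,
#'     drift_px_s = 1)`. The footprint is the `n_px` downsampled blocks
#'     nearest a centre that drifts at `drift_px_s` blocks/s, so the wave
#'     covers exactly `n_px` downsampled pixels throughout its span.}
#'   \item{`cochlea`}{Coordinated cochlear activity. Schedule columns:
#'     `time`, `compartment` (`ISC`/`IHC`/`SGN`), `amplitude`, `duration`.
#'     Geometry: `list(compartments = roi_set(...), ihc_centers =
#'     data.frame(x, y), cell_radius_px = 4, correlation = list(rho,
#'     trace_sd, smooth_frames))`. When `correlation` is given, equicorrelated
#'     smoothed Gaussian traces with pairwise correlation `rho` are added on
#'     the per-IHC discs.}
#'   \item{`crenation`}{Slow local transmittance increases. Schedule columns:
#'     `time`, `cx`, `cy`, `radius_px`, `amplitude`, `duration`; the event
#'     rises linearly over the first 40 percent of `duration` and decays
#'     linearly back.}
#' }
#'
#' @param spec a [movie_gen_spec].
#' @param mode one of `"IC"`, `"SC"`, `"cochlea"`, `"crenation"`.
#' @return a list with `movie` (a [movie_stack]) and `truth` (data frame with
#'   one row per realized event; generator parameters attached as the
#'   `"params"` attribute).
#' @export
gen_widefield_movie <- function(spec, mode = c("IC", "SC", "cochlea",
                                               "crenation")) {
  stopifnot(inherits(spec, "movie_gen_spec"))
  mode <- match.arg(mode)
  with_local_seed(spec$seed, {
    d <- spec$shape
    fps <- spec$frame_rate
    tt <- (seq_len(d[3]) - 1) / fps
    S <- array(0, d)
    sched <- spec$event_schedule
    truth <- NULL
    if (!is.null(sched) && nrow(sched)) {
      truth <- switch(mode,
        IC = {
          ev <- sched
          if (spec$bilateral_ratio > 0) {
            partner <- ev
            partner$lobe <- ifelse(ev$lobe == "left", "right", "left")
            partner$amplitude <- ev$amplitude * spec$bilateral_ratio
            ev$role <- "strong"; partner$role <- "weak"
            ev$pair_id <- seq_len(nrow(ev)); partner$pair_id <- ev$pair_id
            ev <- rbind(ev, partner)
          } else { ev$role <- "strong"; ev$pair_id <- seq_len(nrow(ev)) }
          for (i in seq_len(nrow(ev))) {
            g <- spec$geometry[[ev$lobe[i]]]
            if (is.null(g)) stop("no scan_geometry for lobe ", ev$lobe[i])
            fld <- band_field(d[1:2], g, ev$position_um[i], ev$width_um[i],
                              spec$um_per_px)
            tau <- ev$duration[i] / 3
            kk <- which(tt >= ev$time[i] & tt <= ev$time[i] + 4 * ev$duration[i])
            if (length(kk))
              S <- add_event_frames(S, fld * ev$amplitude[i],
                                    alpha_kernel(tt[kk] - ev$time[i], tau), kk)
          }
          ev[order(ev$time, ev$lobe), ]
        },
        SC = {
          f <- spec$geometry$down_factor %||% 5
          drift <- spec$geometry$drift_px_s %||% 1
          ev <- sched
          ev$measured_duration <- NA_real_
          for (i in seq_len(nrow(ev))) {
            roi <- spec$geometry[[ev$lobe[i]]]
            if (is.null(roi)) stop("no ROI geometry for lobe ", ev$lobe[i])
            # downsampled block grid inside the ROI
            nbr <- floor(roi$h / f); nbc <- floor(roi$w / f)
            bc <- expand.grid(br = seq_len(nbr), bcl = seq_len(nbc))
            c0 <- c(runif(1, 0.25, 0.75) * nbr, runif(1, 0.25, 0.75) * nbc)
            dirv <- runif(1, 0, 2 * pi)
            kk <- which(tt >= ev$time[i] & tt < ev$time[i] + ev$duration[i])
            ev$measured_duration[i] <- length(kk) / fps
            for (k in kk) {
              ctr <- c0 + drift * (tt[k] - ev$time[i]) * c(sin(dirv), cos(dirv))
              dist2 <- (bc$br - ctr[1])^2 + (bc$bcl - ctr[2])^2
              sel <- order(dist2)[seq_len(ev$n_px[i])]
              for (s in sel) {
                rr <- roi$y + (bc$br[s] - 1) * f + 0:(f - 1)
                cc <- roi$x + (bc$bcl[s] - 1) * f + 0:(f - 1)
                S[rr, cc, k] <- S[rr, cc, k] + ev$amplitude[i]
              }
            }
          }
          ev
        },
        cochlea = ,
        crenation = {
          ev <- sched
          for (i in seq_len(nrow(ev))) {
            if (mode == "crenation") {
              nr <- d[1]; nc <- d[2]
              xs <- matrix(rep(seq_len(nc), each = nr), nr, nc) - ev$cx[i]
              ys <- matrix(rep(seq_len(nr), nc), nr, nc) - ev$cy[i]
              fld <- (xs^2 + ys^2 <= ev$radius_px[i]^2) * 1
              rise <- 0.4 * ev$duration[i]
              kk <- which(tt >= ev$time[i] & tt < ev$time[i] + ev$duration[i])
              tr <- tt[kk] - ev$time[i]
              kern <- ifelse(tr < rise, tr / rise,
                             pmax(0, 1 - (tr - rise) / (ev$duration[i] - rise)))
            } else {
              comp <- spec$geometry$compartments[[ev$compartment[i]]]
              if (is.null(comp)) stop("no ROI for compartment ",
                                      ev$compartment[i])
              fld <- roi_mask(comp, d[1:2]) * 1
              tau <- ev$duration[i] / 3
              kk <- which(tt >= ev$time[i] & tt <= ev$time[i] + 4 * ev$duration[i])
              kern <- alpha_kernel(tt[kk] - ev$time[i], tau)
            }
            if (length(kk))
              S <- add_event_frames(S, fld * ev$amplitude[i], kern, kk)
          }
          ev
        })
    }
    if (is.null(truth)) truth <- data.frame(time = numeric(0))
    if (mode == "cochlea" && !is.null(spec$geometry$correlation)) {
      cr <- spec$geometry$correlation
      ctr <- spec$geometry$ihc_centers
      rad <- spec$geometry$cell_radius_px %||% 4
      ncell <- nrow(ctr)
      shared <- rnorm(d[3])
      traces <- sqrt(cr$rho) * matrix(shared, d[3], ncell) +
        sqrt(1 - cr$rho) * matrix(rnorm(d[3] * ncell), d[3], ncell)
      sm <- cr$smooth_frames %||% 5
      if (sm > 1) {
        kern <- exp(-(0:(3 * sm)) / sm); kern <- kern / sum(kern)
        traces <- apply(traces, 2, function(z)
          as.numeric(stats::filter(z, kern, sides = 1, method = "convolution")))
        traces[is.na(traces)] <- 0
      }
      traces <- scale(traces) * (cr$trace_sd %||% 0.05)
      nr <- d[1]; nc <- d[2]
      xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
      ys <- matrix(rep(seq_len(nr), nc), nr, nc)
      for (j in seq_len(ncell)) {
        fld <- ((xs - ctr$x[j])^2 + (ys - ctr$y[j])^2 <= rad^2) * 1
        S <- add_event_frames(S, fld, traces[, j], seq_len(d[3]))
      }
      attr(truth, "correlation_rho") <- cr$rho
    }
    Fm <- spec$baseline * (1 + S)
    if (spec$bleach_tau > 0)
      Fm <- Fm * rep(exp(-tt / spec$bleach_tau), each = d[1] * d[2])
    if (spec$noise_sd > 0)
      Fm <- Fm + array(rnorm(prod(d), 0, spec$noise_sd), d)
    attr(truth, "params") <- list(mode = mode, shape = d, frame_rate = fps,
                                  um_per_px = spec$um_per_px,
                                  baseline = spec$baseline,
                                  bleach_tau = spec$bleach_tau,
                                  noise_sd = spec$noise_sd,
                                  bilateral_ratio = spec$bilateral_ratio,
                                  seed = spec$seed)
    list(movie = movie_stack(Fm, fps, spec$um_per_px), truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
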