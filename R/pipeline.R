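#' Run a reproducible multi-stage analysis from a configuration file
#'
#' Executes the selected stages on synthetic or on-disk inputs, writes every
#' event table as CSV plus a `summary.json`, and records the exact
#' configuration used (`config_used.yml`) so reruns with the same
#' configuration and seed are reproducible. Valid stages: `spikes`,
#' `currents`, `crenation`, `ic`, `sc`, `power`.
#'
#' Each stage entry is a list. With a `synth:` block the stage generates its
#' own input with the named generator parameters; with an `input:` path it
#' loads data written by [write_spike_train], [write_trace] or
#' [write_movie]. Detection parameters go in a `params:` block.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list with elements `seed`, `out_dir` and `stages`.
#' @return (invisibly) a named list of per-stage summaries, also written to
#'   `out_dir/summary.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$out_dir)) stop("config must name an `out_dir`")
  if (is.null(cfg$stages) || !length(cfg$stages))
    stop("config must list at least one stage")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config_used.yml"))
  seed <- cfg$seed %||% 1L
  valid <- c("spikes", "currents", "crenation", "ic", "sc", "power")
  results <- list()
  for (i in seq_along(cfg$stages)) {
    st <- cfg$stages[[i]]
    nm <- st$stage %||% names(cfg$stages)[i]
    if (is.null(nm) || !nm %in% valid)
      stop("unknown stage '", nm, "'; valid stages: ",
           paste(valid, collapse = ", "))
    results[[nm]] <- switch(nm,
      spikes = stage_spikes(st, seed + i, cfg$out_dir),
      currents = stage_currents(st, seed + i, cfg$out_dir),
      crenation = stage_crenation(st, seed + i, cfg$out_dir),
      ic = stage_ic(st, seed + i, cfg$out_dir),
      sc = stage_sc(st, seed + i, cfg$out_dir),
      power = stage_power(st))
  }
  jsonlite::write_json(results, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

# merge a stage's synth parameters with the run seed (stage seed wins)
synth_args <- function(st, seed) {
  args <- st$synth %||% list()
  if (is.null(args$seed)) args$seed <- seed
  args
}

stage_spikes <- function(st, seed, out_dir) {
  train <- if (!is.null(st$input)) read_spike_train(st$input)
  else gen_spike_train(do.call(spike_gen_spec, synth_args(st, seed)))$train
  bursts <- detect_bursts(classify_isis(train),
                          st$params$min_burst_intervals %||% 10)
  metrics <- burst_metrics(bursts, train)
  write_events(cbind(time = bursts$start, bursts),
               file.path(out_dir, "bursts.csv"))
  data.table::fwrite(metrics, file.path(out_dir, "burst_metrics.csv"))
  as.list(metrics)
}

stage_currents <- function(st, seed, out_dir) {
  trace <- if (!is.null(st$input)) read_trace(st$input)
  else {
    args <- synth_args(st, seed)
    if (is.null(args$event_rate)) args$event_rate <- 4
    do.call(gen_current_trace, args)$trace
  }
  det <- detect_current_events(trace,
                               threshold_k = st$params$threshold_k %||% 4)
  write_events(cbind(time = det$events$onset, det$events),
               file.path(out_dir, "current_events.csv"))
  data.table::fwrite(det$epoch_summary,
                     file.path(out_dir, "current_epoch_summary.csv"))
  list(n_events = nrow(det$events),
       freq_per_min = det$epoch_summary$freq_per_min[1])
}

stage_crenation <- function(st, seed, out_dir) {
  movie <- if (!is.null(st$input)) read_movie(st$input)
  else gen_widefield_movie(do.call(movie_gen_spec, synth_args(st, seed)),
                           "crenation")$movie
  res <- crenation_stats(movie, do.call(detection_config,
                                        st$params %||% list()))
  write_events(res$events, file.path(out_dir, "crenations.csv"))
  list(n_events = nrow(res$events), freq_per_min = res$frequency_per_min)
}

stage_ic <- function(st, seed, out_dir) {
  movie <- if (!is.null(st$input)) read_movie(st$input)
  else gen_widefield_movie(do.call(movie_gen_spec, synth_args(st, seed)),
                           "IC")$movie
  dffm <- dff(movie)
  rois <- if (!is.null(st$rois)) read_rois(st$rois, dim(movie$data)[1:2])
  else roi_set(list(
    roi_rect("left", 1, 1, floor(dim(movie$data)[2] / 2),
             dim(movie$data)[1], "lobe"),
    roi_rect("right", floor(dim(movie$data)[2] / 2) + 1, 1,
             ceiling(dim(movie$data)[2] / 2), dim(movie$data)[1], "lobe")))
  ev <- detect_ic_events(dffm, rois,
                         threshold_pct = st$params$threshold_pct %||% 2)
  prs <- match_bilateral(ev, st$params$window %||% 0.5)
  write_events(ev, file.path(out_dir, "ic_events.csv"))
  write_events(prs$pairs, file.path(out_dir, "ic_bilateral_pairs.csv"))
  list(n_events = nrow(ev), n_pairs = nrow(prs$pairs),
       mean_ratio = if (nrow(prs$pairs)) mean(prs$pairs$ratio) else NA)
}

stage_sc <- function(st, seed, out_dir) {
  roi_w <- st$params$roi_w %||% 200
  roi_h <- st$params$roi_h %||% 150
  movie <- if (!is.null(st$input)) read_movie(st$input)
  else gen_widefield_movie(do.call(movie_gen_spec, synth_args(st, seed)),
                           "SC")$movie
  rois <- if (!is.null(st$rois)) read_rois(st$rois, dim(movie$data)[1:2])
  else roi_set(list(roi_rect("left", 1, 1, roi_w, roi_h, "lobe")))
  res <- detect_retinal_waves(movie, rois)
  write_events(cbind(time = res$waves$start, res$waves),
               file.path(out_dir, "retinal_waves.csv"))
  list(n_waves = nrow(res$waves), frequency_per_min = res$frequency_per_min,
       mean_duration = res$mean_duration)
}

stage_power <- function(st) {
  p <- st$params %||% list()
  n <- sample_size_two_means(p$mu1 %||% 10, p$mu2 %||% 7, p$sigma %||% 2,
                             p$alpha %||% 0.05, p$power %||% 0.8,
                             p$ratio %||% 1)
  list(n_per_group = n)
}
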