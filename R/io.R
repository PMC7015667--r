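# Sidecar path for a data file: "<file>.json"
sidecar_path <- function(path) paste0(path, ".json")

#' Read and write image stacks as multi-frame TIFF with a metadata sidecar
#'
#' Stacks are written as multi-frame TIFF plus a JSON sidecar
#' (`<file>.tif.json`) holding `frame_rate`, `um_per_px` and the storage
#' encoding. Integer stacks in `[0, 65535]` are stored as 16-bit samples
#' (lossless round-trip); other stacks are stored as 32-bit floats after an
#' affine rescale to `[0, 1]` recorded in the sidecar (round-trip exact at
#' 32-bit float precision).
#'
#' @param movie a [movie_stack].
#' @param path output `.tif` path.
#' @return `read_movie` returns a [movie_stack]; `write_movie` returns the
#'   path invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  v <- movie$data
  is_int16 <- all(v == round(v)) && min(v) >= 0 && max(v) <= 65535
  d <- dim(v)
  if (is_int16) {
    frames <- lapply(seq_len(d[3]),
                     function(k) matrix(v[, , k] / 65535, d[1], d[2]))
    tiff::writeTIFF(frames, path, bits.per.sample = 16L)
    meta <- list(frame_rate = movie$frame_rate, um_per_px = movie$um_per_px,
                 storage = "uint16")
  } else {
    off <- min(v); sc <- max(v) - off
    if (sc == 0) sc <- 1
    frames <- lapply(seq_len(d[3]),
                     function(k) matrix((v[, , k] - off) / sc, d[1], d[2]))
    tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
    meta <- list(frame_rate = movie$frame_rate, um_per_px = movie$um_per_px,
                 storage = "float32", offset = off, scale = sc)
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path))
    stop("metadata sidecar not found: ", sc_path)
  meta <- jsonlite::fromJSON(sc_path)
  for (f in c("frame_rate", "um_per_px"))
    if (is.null(meta[[f]])) stop("metadata sidecar is missing field `", f, "`")
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  a <- array(unlist(frames), c(dim(frames[[1]]), length(frames)))
  if (identical(meta$storage, "uint16")) {
    a <- round(a * 65535)
  } else {
    a <- a * meta$scale + meta$offset
  }
  movie_stack(a, as.numeric(meta$frame_rate), as.numeric(meta$um_per_px))
}

# format numerics so doubles round-trip exactly through text
fmt17 <- function(x) sprintf("%.17g", x)

#' Read and write current traces as two-column CSV with a metadata sidecar
#'
#' The CSV has columns `time_s`, `value_pA` (UTF-8, header row, full double
#' precision); the JSON sidecar (`<file>.json`) holds `rate_hz`, `epochs`
#' and `holding_potential`.
#'
#' @param trace a [current_trace].
#' @param path output `.csv` path.
#' @return `read_trace` returns a [current_trace]; `write_trace` the path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  dt <- data.table::data.table(time_s = fmt17(trace_times(trace)),
                               value_pA = fmt17(trace$samples))
  data.table::fwrite(dt, path, quote = FALSE)
  jsonlite::write_json(
    list(rate_hz = trace$rate_hz, epochs = trace$epochs,
         holding_potential = trace$holding_potential),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) stop("metadata sidecar not found: ", sc_path)
  meta <- jsonlite::fromJSON(sc_path)
  if (is.null(meta$rate_hz)) stop("metadata sidecar is missing field `rate_hz`")
  dt <- data.table::fread(path)
  if (!all(c("time_s", "value_pA") %in% names(dt)))
    stop("trace CSV must have columns time_s, value_pA")
  bad <- which(!is.finite(dt$value_pA))
  if (length(bad))
    stop("malformed trace values at line(s): ",
         paste(head(bad + 1L, 5), collapse = ", "))
  epochs <- meta$epochs
  if (!is.null(epochs)) epochs <- lapply(epochs, as.numeric)
  hp <- meta$holding_potential
  current_trace(dt$value_pA, as.numeric(meta$rate_hz), epochs = epochs,
                holding_potential = if (is.null(hp)) NA_real_
                else as.numeric(hp))
}

#' Read and write event tables as CSV
#'
#' Event tables are plain CSV with a header row. On write, rows are sorted
#' by the `time` column when present; on read, unsorted files are sorted.
#'
#' @param events a data frame.
#' @param path file path.
#' @return `read_events` returns a data frame; `write_events` the path.
#' @export
write_events <- function(events, path) {
  if ("time" %in% names(events))
    events <- events[order(events$time), , drop = FALSE]
  data.table::fwrite(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- as.data.frame(data.table::fread(path))
  if ("time" %in% names(ev)) ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Read and write spike trains as single-column CSV with a sidecar
#'
#' @param train a [spike_train].
#' @param path output `.csv` path (column `time_s`); the sidecar holds
#'   `duration` and `source_id`.
#' @return `read_spike_train` returns a [spike_train]; `write_spike_train`
#'   the path.
#' @export
write_spike_train <- function(train, path) {
  stopifnot(inherits(train, "spike_train"))
  data.table::fwrite(data.table::data.table(time_s = fmt17(train$times)),
                     path, quote = FALSE)
  jsonlite::write_json(list(duration = train$duration,
                            source_id = train$source_id),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path) {
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) stop("metadata sidecar not found: ", sc_path)
  meta <- jsonlite::fromJSON(sc_path)
  if (is.null(meta$duration))
    stop("metadata sidecar is missing field `duration`")
  dt <- data.table::fread(path)
  spike_train(sort(dt$time_s), as.numeric(meta$duration),
              meta$source_id %||% NA_character_)
}
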