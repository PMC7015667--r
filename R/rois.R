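#' Region-of-interest set
#'
#' A list of named ROIs in pixel coordinates (`x` = column, `y` = row,
#' 1-based). Supported shapes: `rect` (`x`, `y`, `w`, `h`; top-left corner
#' plus size), `ellipse` (`cx`, `cy`, `rx`, `ry`), and `polygon` (`x`, `y`
#' vertex vectors). Each ROI carries a compartment label
#' (`ISC`, `IHC`, `SGN`, `lobe`, `whole_field`, ...).
#'
#' @param rois list of ROI descriptions; each a list with `name`, `shape`,
#'   `compartment` and the shape parameters above.
#' @return an object of class `roi_set`.
#' @export
roi_set <- function(rois) {
  stopifnot(is.list(rois), length(rois) > 0)
  for (r in rois) {
    if (is.null(r$name) || is.null(r$shape))
      stop("every ROI needs `name` and `shape`")
    if (!r$shape %in% c("rect", "ellipse", "polygon"))
      stop("unknown ROI shape: ", r$shape)
  }
  names(rois) <- vapply(rois, `[[`, character(1), "name")
  structure(rois, class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

# Helper constructors ---------------------------------------------------------

#' @rdname roi_set
#' @param name,compartment ROI name and compartment label.
#' @param x,y top-left corner (rect) or vertex vectors (polygon), px.
#' @param w,h rectangle width/height, px.
#' @export
roi_rect <- function(name, x, y, w, h, compartment = "whole_field")
  list(name = name, shape = "rect", compartment = compartment,
       x = x, y = y, w = w, h = h)

#' @rdname roi_set
#' @param cx,cy,rx,ry ellipse centre and radii, px.
#' @export
roi_ellipse <- function(name, cx, cy, rx, ry, compartment = "whole_field")
  list(name = name, shape = "ellipse", compartment = compartment,
       cx = cx, cy = cy, rx = rx, ry = ry)

#' @rdname roi_set
#' @export
roi_polygon <- function(name, x, y, compartment = "whole_field")
  list(name = name, shape = "polygon", compartment = compartment, x = x, y = y)

# Logical pixel mask of one ROI on a rows x cols frame.
roi_mask <- function(roi, dims) {
  nr <- dims[1]; nc <- dims[2]
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)  # x
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)         # y
  m <- switch(roi$shape,
    rect = rows >= roi$y & rows < roi$y + roi$h &
           cols >= roi$x & cols < roi$x + roi$w,
    ellipse = ((cols - roi$cx) / roi$rx)^2 + ((rows - roi$cy) / roi$ry)^2 <= 1,
    polygon = {
      bnd <- cbind(c(roi$x, roi$x[1]), c(roi$y, roi$y[1]))
      inside <- mgcv::in.out(bnd, cbind(as.vector(cols), as.vector(rows)))
      matrix(inside, nr, nc)
    })
  if (!any(m)) stop("ROI '", roi$name, "' covers no pixels of the frame")
  m
}

roi_centroid <- function(roi) {
  switch(roi$shape,
    rect = c(x = roi$x + roi$w / 2, y = roi$y + roi$h / 2),
    ellipse = c(x = roi$cx, y = roi$cy),
    polygon = c(x = mean(roi$x), y = mean(roi$y)))
}

# Mean trace of a dff_movie (or movie_stack) within one ROI, per frame.
roi_trace <- function(x, roi) {
  v <- if (inherits(x, "dff_movie")) x$dff else x$data
  d <- dim(v)
  m <- roi_mask(roi, d[1:2])
  dim(v) <- c(d[1] * d[2], d[3])
  colMeans(v[as.vector(m), , drop = FALSE])
}

#' Read / write ROI geometry JSON
#'
#' ROI sets are stored as a JSON array of objects with `name`, `shape`,
#' `compartment` and shape parameters in pixel coordinates.
#'
#' @param path file path.
#' @param frame_dim optional `c(rows, cols)`; when given, ROI vertices and
#'   extents are validated against the frame bounds.
#' @return a [roi_set].
#' @export
read_rois <- function(path, frame_dim = NULL) {
  rois <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  rs <- roi_set(rois)
  if (!is.null(frame_dim)) {
    for (r in rs) {
      xs <- switch(r$shape,
                   rect = c(r$x, r$x + r$w - 1), ellipse = c(r$cx - r$rx, r$cx + r$rx),
                   polygon = range(r$x))
      ys <- switch(r$shape,
                   rect = c(r$y, r$y + r$h - 1), ellipse = c(r$cy - r$ry, r$cy + r$ry),
                   polygon = range(r$y))
      if (min(xs) < 1 || max(xs) > frame_dim[2] ||
          min(ys) < 1 || max(ys) > frame_dim[1])
        stop("ROI '", r$name, "' extends outside the frame bounds")
    }
  }
  rs
}

#' @rdname read_rois
#' @param rois a [roi_set] to write.
#' @export
write_rois <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  jsonlite::write_json(unname(unclass(rois)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
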