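#' Region-of-interest specification
#'
#' Regions are carried as pixel masks so that arbitrary polygonal, banded or
#' per-column geometries share one representation. Pixel coordinates are
#' 1-based row/column indices (row 1 at the top); the bone long axis runs
#' along the columns ("vertical"), with the metaphysis at larger row
#' indices.
#'
#' @param label region label, e.g. one of `cortex`, `epiphysis`,
#'   `metaphysis`, `primary_spongiosa`, `secondary_spongiosa`,
#'   `growth_plate_band`.
#' @param mask logical matrix, `TRUE` inside the region.
#' @param axis direction of the bone long axis; only `"vertical"` is
#'   implemented.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(label, mask, axis = "vertical") {
  stopifnot(is.matrix(mask), is.logical(mask))
  axis <- match.arg(axis, "vertical")
  if (!any(mask))
    oq_stop(sprintf("ROI '%s' is empty", label), "oq_empty_roi_error")
  structure(list(label = label, mask = mask, axis = axis),
            class = "roi_spec")
}

#' Axis-aligned rectangular ROI
#' @param label region label.
#' @param rows,cols integer index vectors of the rectangle.
#' @param dim image dimensions `c(nrow, ncol)`.
#' @param axis direction of the bone long axis.
#' @return a [roi_spec()].
#' @export
roi_rect <- function(label, rows, cols, dim, axis = "vertical") {
  if (any(rows < 1 | rows > dim[1]) || any(cols < 1 | cols > dim[2]))
    oq_stop("ROI rectangle exceeds image bounds", "oq_domain_error")
  m <- matrix(FALSE, dim[1], dim[2])
  m[rows, cols] <- TRUE
  roi_spec(label, m, axis)
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("roi_spec '%s': %d px in a %d x %d raster\n",
              x$label, sum(x$mask), nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Binary mineral mask from a calcium map
#'
#' Pixel-wise comparison of calcium content against a fixed threshold; the
#' default 5.2 wt\%Ca is the mineralized/unmineralized boundary used
#' throughout the pipeline. Off-sample pixels are `FALSE` in the mask and
#' recorded separately.
#'
#' @param camap a [ca_map()].
#' @param threshold wt\%Ca boundary.
#' @return object of class `mineral_mask` with `mask` (logical),
#'   `off_sample` (logical or `NULL`), `threshold`, `pixel_size`.
#' @export
make_mineral_mask <- function(camap, threshold = 5.2) {
  stopifnot(inherits(camap, "ca_map"), threshold >= 0)
  off <- is.na(camap$values)
  m <- !off & camap$values >= threshold
  structure(list(mask = m,
                 off_sample = if (any(off)) off else NULL,
                 threshold = threshold,
                 pixel_size = camap$pixel_size),
            class = "mineral_mask")
}

#' Wrap an existing binary raster as a mineral mask
#' @param mask logical matrix, `TRUE` = mineralized.
#' @param pixel_size micrometers per pixel.
#' @param threshold threshold recorded as provenance, wt\%Ca.
#' @param off_sample optional logical matrix of off-sample pixels.
#' @return object of class `mineral_mask`.
#' @export
mineral_mask <- function(mask, pixel_size = 0.88, threshold = 5.2,
                         off_sample = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask), pixel_size > 0)
  structure(list(mask = mask, off_sample = off_sample,
                 threshold = threshold, pixel_size = pixel_size),
            class = "mineral_mask")
}

#' @export
print.mineral_mask <- function(x, ...) {
  cat(sprintf("mineral_mask: %d x %d px, %.1f%% mineralized (Ca >= %.2f wt%%)\n",
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask), x$threshold))
  invisible(x)
}
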