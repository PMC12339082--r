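# Growth-plate band location and the metaphyseal mineralization front.
#
# The growth plate appears as a transverse unmineralized band separating the
# epiphyseal and metaphyseal mineralized compartments. Band search runs on a
# morphologically opened copy of the mask (3x3 box) so single-pixel noise
# cannot fabricate or pierce the band. Cortex-like columns (almost fully
# mineralized top to bottom) carry no band and are excluded from the row
# profile and from all per-column measurements.

find_gp_band <- function(m, band_frac = 0.05, cortex_frac = 0.85,
                         min_band_px = 8) {
  col_fill <- colMeans(m)
  cand <- which(col_fill < cortex_frac)
  if (!length(cand))
    oq_stop("no trabecular columns: image looks fully mineralized",
            "oq_front_not_found_error")
  profile <- rowMeans(m[, cand, drop = FALSE])
  low <- profile <= band_frac
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_band_px)
  # interior runs only: margins above/below the section are also empty
  interior <- runs[starts[runs] > 1L & ends[runs] < length(profile)]
  if (!length(interior))
    oq_stop("no transverse unmineralized band detected",
            "oq_front_not_found_error")
  # the growth plate is bounded by densely mineralized fronts on both
  # sides; score candidate runs by their boundary fill so that chance
  # alignments of inter-trabecular marrow (bounded only by sparse rows)
  # cannot outrank it, then break ties by run length
  boundary_fill <- function(k) {
    above <- max(1L, starts[k] - 3L):(starts[k] - 1L)
    below <- (ends[k] + 1L):min(length(profile), ends[k] + 3L)
    min(max(profile[above]), max(profile[below]))
  }
  score <- vapply(interior, boundary_fill, numeric(1))
  top <- interior[score > max(score) - 1e-9]
  best <- top[which.max(r$lengths[top])]
  band <- c(starts[best], ends[best])
  list(band_rows = band, center = as.integer(floor(mean(band))),
       candidate_cols = cand)
}

#' Detect the metaphyseal mineralization front
#'
#' For every candidate (non-cortical) image column the front is the first
#' mineralized pixel on the metaphyseal side of the growth-plate band.
#' Columns without a crossing, or occluded by a mineralized bridge through
#' the band center, are flagged invalid.
#'
#' @param mask a `mineral_mask` (see [make_mineral_mask()]).
#' @param opening number of 3x3 binary opening passes applied before band
#'   search (0 disables).
#' @param band_frac maximum mineralized row-fraction inside the band.
#' @param cortex_frac column mineralized fraction at or above which a column
#'   is treated as cortex and excluded.
#' @param min_band_px minimum band height in pixels.
#' @return object of class `mineralization_front`: `front` (per-column row
#'   index of the first metaphyseal mineralized pixel, `NA` where invalid),
#'   `valid`, `band_rows`, `center`, `dim`, `pixel_size`.
#' @export
detect_mineralization_front <- function(mask, opening = 1, band_frac = 0.05,
                                        cortex_frac = 0.85, min_band_px = 8) {
  stopifnot(inherits(mask, "mineral_mask"))
  m <- mask$mask
  if (opening > 0)
    m <- .binary_open3(as_int_mask(m), as.integer(opening)) > 0L
  band <- find_gp_band(m, band_frac, cortex_frac, min_band_px)
  nr <- nrow(m)
  front <- rep(NA_integer_, ncol(m))
  for (j in band$candidate_cols) {
    if (m[band$center, j]) next  # bridge through the band: occluded
    below <- which(m[band$center:nr, j])
    if (length(below)) front[j] <- band$center + below[1] - 1L
  }
  if (!any(!is.na(front)))
    oq_stop("no column crosses into a mineralized metaphysis",
            "oq_front_not_found_error")
  structure(list(front = front, valid = !is.na(front),
                 band_rows = band$band_rows, center = band$center,
                 dim = dim(m), pixel_size = mask$pixel_size),
            class = "mineralization_front")
}

#' @export
print.mineralization_front <- function(x, ...) {
  cat(sprintf(
    "mineralization front: band rows %d-%d, %d/%d valid columns, median front row %d\n",
    x$band_rows[1], x$band_rows[2], sum(x$valid), length(x$valid),
    stats::median(x$front, na.rm = TRUE)))
  invisible(x)
}

#' Primary- and secondary-spongiosa band ROIs below the front
#'
#' The primary spongiosa is the band extending `primary_um` (default 500 um)
#' along the bone axis from the per-column mineralization front; the
#' secondary spongiosa is the following `secondary_um` (default 1000 um).
#' Band depths are converted to pixels by rounding to the nearest integer
#' count; intervals are half-open and clipped to the image with a warning.
#'
#' @param front a `mineralization_front`.
#' @param pixel_size micrometers per pixel; defaults to the front's.
#' @param primary_um,secondary_um band depths along the axis, micrometers.
#' @return list with [roi_spec()] elements `primary` and `secondary`.
#' @export
define_spongiosa_rois <- function(front, pixel_size = NULL,
                                  primary_um = 500, secondary_um = 1000) {
  stopifnot(inherits(front, "mineralization_front"))
  ps <- pixel_size %||% front$pixel_size
  d1 <- round(primary_um / ps)
  d2 <- round(secondary_um / ps)
  nr <- front$dim[1]
  cols <- which(front$valid)
  band_mask <- function(start_offset, depth) {
    m <- matrix(FALSE, nr, front$dim[2])
    starts <- front$front[cols] + start_offset
    rows <- rep(starts, each = depth) + rep(seq_len(depth) - 1L,
                                            times = length(cols))
    cc <- rep(cols, each = depth)
    keep <- rows <= nr
    if (!any(keep)) return(NULL)
    clipped <- !all(keep)
    m[cbind(rows[keep], cc[keep])] <- TRUE
    list(mask = m, clipped = clipped)
  }
  p <- band_mask(0L, d1)
  s <- band_mask(d1, d2)
  if (is.null(p))
    oq_stop("primary-spongiosa band lies entirely outside the image",
            "oq_empty_roi_error")
  if (is.null(s))
    oq_stop("secondary-spongiosa band lies entirely outside the image",
            "oq_empty_roi_error")
  if (p$clipped || s$clipped)
    warning("spongiosa band clipped at the image boundary")
  list(primary = roi_spec("primary_spongiosa", p$mask),
       secondary = roi_spec("secondary_spongiosa", s$mask))
}

#' Thickness of the unmineralized growth-plate zone
#'
#' Measures, per valid column, the distance in micrometers between the last
#' epiphyseal mineralized pixel above the growth-plate band and the first
#' metaphyseal mineralized pixel below it — the unmineralized resting plus
#' proliferative cartilage zone. Columns occluded by a mineralized bridge,
#' or whose band runs into the image border, are excluded.
#'
#' @inheritParams detect_mineralization_front
#' @return object of class `growth_plate_result`: `mean_thickness` (um),
#'   `per_column_thickness` (um, `NA` where invalid), `n_valid_columns`.
#' @export
growth_plate_thickness <- function(mask, opening = 1, band_frac = 0.05,
                                   cortex_frac = 0.85, min_band_px = 8) {
  stopifnot(inherits(mask, "mineral_mask"))
  m <- mask$mask
  if (opening > 0)
    m <- .binary_open3(as_int_mask(m), as.integer(opening)) > 0L
  band <- find_gp_band(m, band_frac, cortex_frac, min_band_px)
  nr <- nrow(m)
  th <- rep(NA_real_, ncol(m))
  for (j in band$candidate_cols) {
    if (m[band$center, j]) next
    above <- which(m[seq_len(band$center - 1L), j])
    below <- which(m[band$center:nr, j])
    if (!length(above) || !length(below)) next
    up <- above[length(above)]
    down <- band$center + below[1] - 1L
    th[j] <- (down - up - 1) * mask$pixel_size
  }
  n_valid <- sum(!is.na(th))
  if (n_valid == 0L)
    oq_stop("no valid columns across the growth-plate band",
            "oq_front_not_found_error")
  structure(list(mean_thickness = mean(th, na.rm = TRUE),
                 per_column_thickness = th,
                 n_valid_columns = n_valid,
                 band_rows = band$band_rows,
                 pixel_size = mask$pixel_size),
            class = "growth_plate_result")
}

#' @export
print.growth_plate_result <- function(x, ...) {
  cat(sprintf("growth plate: mean unmineralized thickness %.1f um over %d columns\n",
              x$mean_thickness, x$n_valid_columns))
  invisible(x)
}
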