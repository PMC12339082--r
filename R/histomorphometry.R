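#' Bone area fraction (BV/TV) inside a region
#'
#' BV/TV is the 2D surrogate of bone volume per tissue volume: the
#' mineralized pixel area divided by the region area.
#'
#' @param mask a `mineral_mask`.
#' @param roi a [roi_spec()].
#' @return object of class `histomorph_result` with `bv_tv` (percent),
#'   `bone_area` and `tissue_area` (um^2), `region_label`.
#' @export
bv_tv <- function(mask, roi) {
  stopifnot(inherits(mask, "mineral_mask"), inherits(roi, "roi_spec"))
  if (!identical(dim(roi$mask), dim(mask$mask)))
    oq_stop("ROI geometry does not match the mask", "oq_domain_error")
  n_roi <- sum(roi$mask)
  if (n_roi == 0L)
    oq_stop("empty ROI", "oq_empty_roi_error")
  n_bone <- sum(mask$mask & roi$mask)
  a <- mask$pixel_size^2
  structure(list(bv_tv = 100 * n_bone / n_roi,
                 bone_area = n_bone * a,
                 tissue_area = n_roi * a,
                 region_label = roi$label,
                 pixel_size = mask$pixel_size),
            class = "histomorph_result")
}

#' @export
print.histomorph_result <- function(x, ...) {
  cat(sprintf("%s: BV/TV %.1f%% (bone %.3g um^2 / tissue %.3g um^2)\n",
              x$region_label, x$bv_tv, x$bone_area, x$tissue_area))
  invisible(x)
}

#' Trabecular thickness from the local-thickness field
#'
#' Tb.Th is the area-weighted mean of the 2D local thickness of the
#' mineralized phase: each mineralized pixel is assigned the diameter of the
#' largest disc inscribed in the phase that contains it (computed from the
#' Euclidean distance transform), and the mean is taken over the ROI. The
#' estimator is assumption-free on section rasters, unlike plate-model
#' formulas.
#'
#' The thickness field is evaluated on the ROI bounding box extended by
#' `pad_px` pixels so discs anchored just outside the band are seen; treat
#' `pad_px` as at least the largest expected trabecular width in pixels.
#'
#' @param mask a `mineral_mask`.
#' @param roi a [roi_spec()]; `NULL` evaluates the whole raster.
#' @param pad_px bounding-box padding in pixels.
#' @return Tb.Th in micrometers.
#' @export
trabecular_thickness <- function(mask, roi = NULL, pad_px = 64) {
  stopifnot(inherits(mask, "mineral_mask"))
  m <- mask$mask
  if (is.null(roi)) {
    sel_rows <- seq_len(nrow(m)); sel_cols <- seq_len(ncol(m))
    roi_mask <- NULL
  } else {
    stopifnot(inherits(roi, "roi_spec"))
    if (!identical(dim(roi$mask), dim(m)))
      oq_stop("ROI geometry does not match the mask", "oq_domain_error")
    rs <- range(which(rowSums(roi$mask) > 0))
    cs <- range(which(colSums(roi$mask) > 0))
    sel_rows <- max(1, rs[1] - pad_px):min(nrow(m), rs[2] + pad_px)
    sel_cols <- max(1, cs[1] - pad_px):min(ncol(m), cs[2] + pad_px)
    roi_mask <- roi$mask[sel_rows, sel_cols]
  }
  sub <- m[sel_rows, sel_cols]
  sel <- if (is.null(roi_mask)) sub else sub & roi_mask
  if (!any(sel))
    oq_stop("no mineralized pixels in ROI", "oq_empty_phase_error")
  lt <- .local_thickness_px(as_int_mask(sub))
  mean(lt[sel]) * mask$pixel_size
}

#' Trabecular number under the plate model
#'
#' Tb.N is derived from the two measured quantities as
#' `(BV/TV / 100) / Tb.Th`, converted to plates per millimeter.
#'
#' @param bv_tv bone area fraction, percent.
#' @param tb_th trabecular thickness, micrometers.
#' @return Tb.N in 1/mm.
#' @export
trabecular_number <- function(bv_tv, tb_th) {
  if (!is.finite(tb_th) || tb_th <= 0)
    oq_stop("Tb.Th must be positive", "oq_division_error")
  stopifnot(bv_tv >= 0, bv_tv <= 100)
  (bv_tv / 100) / tb_th * 1000
}

#' Local thickness field of a binary phase
#'
#' Exposes the per-pixel local thickness (largest-inscribed-disc diameter)
#' underlying [trabecular_thickness()].
#'
#' @param mask logical matrix, `TRUE` = phase of interest.
#' @param pixel_size micrometers per pixel.
#' @return numeric matrix of thickness values in micrometers (0 off-phase).
#' @export
local_thickness <- function(mask, pixel_size = 1) {
  stopifnot(is.matrix(mask))
  .local_thickness_px(as_int_mask(mask)) * pixel_size
}
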