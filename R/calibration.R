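#' Canonical qBEI calibration constants
#'
#' Backscattered-electron gray levels are standardized against pure carbon
#' and aluminum reference materials. On the canonical (post-rescale) gray
#' scale the carbon standard sits at `carbon_gl_canonical`, the aluminum
#' standard at `aluminum_gl_canonical`, and calcium content grows linearly
#' at `slope` weight-percent calcium per canonical gray-level step, starting
#' from zero at `zero_gl_canonical`.
#'
#' @param carbon_gl_canonical canonical gray level of the carbon standard.
#' @param aluminum_gl_canonical canonical gray level of the aluminum standard.
#' @param slope wt\%Ca per canonical gray-level step.
#' @param zero_gl_canonical canonical gray level at which Ca = 0.
#' @return a list of calibration constants.
#' @export
qbei_constants <- function(carbon_gl_canonical = 25,
                           aluminum_gl_canonical = 225,
                           slope = 0.17,
                           zero_gl_canonical = 25) {
  stopifnot(carbon_gl_canonical < aluminum_gl_canonical, slope > 0)
  list(carbon_gl_canonical = carbon_gl_canonical,
       aluminum_gl_canonical = aluminum_gl_canonical,
       slope = slope,
       zero_gl_canonical = zero_gl_canonical)
}

#' Fit the two-point gray-level to calcium calibration
#'
#' Affine model in two stages: measured gray levels are first rescaled so the
#' measured carbon and aluminum standards land on their canonical positions,
#' then canonical gray maps linearly to wt\%Ca with the fixed canonical slope.
#' Instrument drift in the standards is thereby absorbed completely.
#'
#' @param carbon_gl_measured measured gray level of the carbon standard (0-255).
#' @param aluminum_gl_measured measured gray level of the aluminum standard.
#' @param config calibration constants, see [qbei_constants()].
#' @return an object of class `qbei_calibration` with elements `slope`
#'   (wt\%Ca per canonical step), `offset_gl` (measured gray level at which
#'   Ca = 0), the measured and canonical standard positions, and the gain of
#'   the measured-to-canonical rescale.
#' @export
#' @examples
#' m <- fit_calibration(25, 225)
#' calibrate_gray(m, 125)  # wt%Ca at mid-scale
fit_calibration <- function(carbon_gl_measured, aluminum_gl_measured,
                            config = qbei_constants()) {
  if (!is.finite(carbon_gl_measured) || !is.finite(aluminum_gl_measured) ||
      carbon_gl_measured < 0 || aluminum_gl_measured > 255)
    oq_stop("standard gray levels must lie in [0, 255]", "oq_domain_error")
  if (aluminum_gl_measured <= carbon_gl_measured)
    oq_stop("aluminum standard must backscatter brighter than carbon",
            "oq_invalid_standards_error")
  gain <- (config$aluminum_gl_canonical - config$carbon_gl_canonical) /
    (aluminum_gl_measured - carbon_gl_measured)
  # measured gray level whose canonical image is the zero-calcium position
  offset_gl <- carbon_gl_measured +
    (config$zero_gl_canonical - config$carbon_gl_canonical) / gain
  structure(list(slope = config$slope,
                 offset_gl = offset_gl,
                 gain = gain,
                 carbon_gl_measured = carbon_gl_measured,
                 aluminum_gl_measured = aluminum_gl_measured,
                 carbon_gl_canonical = config$carbon_gl_canonical,
                 aluminum_gl_canonical = config$aluminum_gl_canonical,
                 zero_gl_canonical = config$zero_gl_canonical),
            class = "qbei_calibration")
}

#' Map measured gray levels to canonical gray levels
#' @param model a `qbei_calibration`.
#' @param gl measured gray level(s).
#' @return canonical gray level(s).
#' @export
canonical_gray <- function(model, gl) {
  model$carbon_gl_canonical + (gl - model$carbon_gl_measured) * model$gain
}

#' Convert measured gray levels to calcium weight-percent (unclipped)
#' @inheritParams canonical_gray
#' @return wt\%Ca value(s); may be negative below the zero-calcium offset.
#' @export
calibrate_gray <- function(model, gl) {
  model$slope * (canonical_gray(model, gl) - model$zero_gl_canonical)
}

#' Invert the calibration: gray level for a given calcium content
#' @param model a `qbei_calibration`.
#' @param ca wt\%Ca value(s).
#' @return measured-scale gray level(s), continuous (not rounded).
#' @export
gray_from_ca <- function(model, ca) {
  canonical <- model$zero_gl_canonical + ca / model$slope
  model$carbon_gl_measured +
    (canonical - model$carbon_gl_canonical) / model$gain
}

#' @export
print.qbei_calibration <- function(x, ...) {
  cat("qBEI two-point calibration\n")
  cat(sprintf("  standards (measured): C = %.1f, Al = %.1f gray levels\n",
              x$carbon_gl_measured, x$aluminum_gl_measured))
  cat(sprintf("  canonical anchors:    C = %g, Al = %g\n",
              x$carbon_gl_canonical, x$aluminum_gl_canonical))
  cat(sprintf("  slope: %.3f wt%%Ca per canonical step; Ca = 0 at measured gray %.2f\n",
              x$slope, x$offset_gl))
  invisible(x)
}

#' Calcium map container
#'
#' A calibrated raster of calcium weight-percent values. Off-sample pixels
#' (embedding resin outside the section, if a sample mask was supplied) are
#' carried as `NA`.
#'
#' @param values numeric matrix of wt\%Ca, `NA` marking off-sample pixels.
#' @param pixel_size pixel edge length in micrometers.
#' @param calibration optional `qbei_calibration` used to produce the map.
#' @return an object of class `ca_map`.
#' @export
ca_map <- function(values, pixel_size = 0.88, calibration = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    oq_stop("values must be a numeric matrix", "oq_format_error")
  if (pixel_size <= 0)
    oq_stop("pixel_size must be positive", "oq_domain_error")
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 45))
    oq_stop("on-sample calcium values must lie in [0, 45] wt%Ca",
            "oq_domain_error")
  structure(list(values = values, pixel_size = pixel_size,
                 calibration = calibration),
            class = "ca_map")
}

#' Apply a fitted calibration to a raw 8-bit image
#'
#' @param raw integer/numeric matrix of raw gray levels (0-255), single
#'   channel.
#' @param model a `qbei_calibration`.
#' @param pixel_size pixel edge length in micrometers.
#' @param sample_mask optional logical matrix, `TRUE` on-sample; `FALSE`
#'   pixels become `NA` in the map. Without a mask all pixels are candidates
#'   and the downstream mineralization threshold separates bone from
#'   embedding.
#' @return a [ca_map()]; calcium is clipped at 0 from below (gray levels
#'   below the zero-calcium offset are organic matrix / embedding and carry
#'   no mineral signal).
#' @export
apply_calibration <- function(raw, model, pixel_size = 0.88,
                              sample_mask = NULL) {
  if (length(dim(raw)) == 3L)
    oq_stop("multi-channel input: qBEI rasters must be single-channel",
            "oq_format_error")
  if (!is.matrix(raw) || !is.numeric(raw))
    oq_stop("raw must be a single-channel numeric matrix", "oq_format_error")
  if (!inherits(model, "qbei_calibration"))
    oq_stop("model must be a qbei_calibration", "oq_domain_error")
  ca <- calibrate_gray(model, raw)
  ca[ca < 0] <- 0
  if (!is.null(sample_mask)) {
    stopifnot(identical(dim(sample_mask), dim(raw)))
    ca[!sample_mask] <- NA_real_
  }
  ca_map(ca, pixel_size = pixel_size, calibration = model)
}

#' @export
print.ca_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("ca_map: %d x %d px at %.2f um/px (%d on-sample px)\n",
              nrow(x$values), ncol(x$values), x$pixel_size, length(v)))
  if (length(v))
    cat(sprintf("  Ca range %.2f - %.2f wt%%, mean %.2f\n",
                min(v), max(v), mean(v)))
  invisible(x)
}
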