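# Osteocyte lacuna sections: enclosed unmineralized voids in the mineralized
# matrix, gated by section area.

dilate3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rt <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    ct <- max(1, 1 - dc):min(nc, nc - dc)
    out[rt, ct] <- out[rt, ct] | m[rs, cs]
  }
  out
}

# Crofton 4-direction perimeter, in pixel units, for every label of a
# labelled raster. Transitions are counted along horizontal, vertical and
# both diagonal line families; diagonal families have line spacing 1/sqrt(2).
crofton_perimeter <- function(lab, n_labels) {
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lab
  count_dir <- function(a, b) {
    d <- a != b
    v <- c(a[d], b[d])
    tabulate(v[v > 0L], nbins = n_labels)
  }
  nrp <- nr + 2L; ncp <- nc + 2L
  n_h <- count_dir(pad[, -ncp], pad[, -1])
  n_v <- count_dir(pad[-nrp, ], pad[-1, ])
  n_d1 <- count_dir(pad[-nrp, -ncp], pad[-1, -1])
  n_d2 <- count_dir(pad[-nrp, -1], pad[-1, -ncp])
  (pi / 8) * (n_h + n_v + (n_d1 + n_d2) / sqrt(2))
}

#' Extract osteocyte lacuna sections from a mineral mask
#'
#' Lacuna sections are connected components of unmineralized pixels
#' (8-connectivity) fully enclosed by the mineralized matrix: components
#' touching the raster border, or 8-adjacent to an off-sample pixel, are
#' discarded (this removes marrow space and vascular canals connected to
#' the outside). Surviving components are gated by section area, inclusive
#' bounds.
#'
#' @param mask a `mineral_mask`.
#' @param min_area,max_area area gate in um^2 (defaults 5 and 200).
#' @param roi optional [roi_spec()]; only components whose centroid falls
#'   inside the region are kept.
#' @return a data.frame of class `ols_records` with columns `id`,
#'   `area_um2` (pixel count times pixel area), `perimeter_um` (Crofton
#'   4-direction estimator), `cx`, `cy` (centroid, 1-based pixel
#'   coordinates, x = column). Attributes record pixel size and provenance.
#' @export
extract_ols <- function(mask, min_area = 5, max_area = 200, roi = NULL) {
  stopifnot(inherits(mask, "mineral_mask"))
  if (!(min_area > 0 && min_area < max_area))
    oq_stop("need 0 < min_area < max_area", "oq_domain_error")
  voids <- !mask$mask
  if (!is.null(mask$off_sample)) voids <- voids & !mask$off_sample
  lab <- .label_components(as_int_mask(voids), 8L)
  k <- max(lab)
  empty <- data.frame(id = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), cx = numeric(0),
                      cy = numeric(0))
  if (k == 0L)
    return(structure(empty, class = c("ols_records", "data.frame"),
                     pixel_size = mask$pixel_size, mask_dim = dim(mask$mask)))
  nr <- nrow(lab); nc <- ncol(lab)
  # enclosure: border contact or adjacency to off-sample disqualifies
  excluded <- logical(k)
  border <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  excluded[border[border > 0L]] <- TRUE
  if (!is.null(mask$off_sample)) {
    near_off <- dilate3(mask$off_sample)
    touch <- unique(lab[near_off & lab > 0L])
    excluded[touch] <- TRUE
  }
  px_area <- mask$pixel_size^2
  areas_px <- tabulate(lab[lab > 0L], nbins = k)
  areas <- areas_px * px_area
  keep <- !excluded & areas >= min_area & areas <= max_area
  if (!any(keep))
    return(structure(empty, class = c("ols_records", "data.frame"),
                     pixel_size = mask$pixel_size, mask_dim = dim(mask$mask)))
  per <- crofton_perimeter(lab, k) * mask$pixel_size
  inside <- lab > 0L
  rows_sum <- rowsum(as.numeric(row(lab)[inside]), lab[inside])
  cols_sum <- rowsum(as.numeric(col(lab)[inside]), lab[inside])
  ids <- which(keep)
  rec <- data.frame(id = seq_along(ids),
                    area_um2 = areas[ids],
                    perimeter_um = per[ids],
                    cx = cols_sum[ids] / areas_px[ids],
                    cy = rows_sum[ids] / areas_px[ids])
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "roi_spec"))
    inside_roi <- roi$mask[cbind(pmin(pmax(round(rec$cy), 1), nr),
                                 pmin(pmax(round(rec$cx), 1), nc))]
    rec <- rec[inside_roi, , drop = FALSE]
    rec$id <- seq_len(nrow(rec))
  }
  structure(rec, class = c("ols_records", "data.frame"),
            pixel_size = mask$pixel_size, mask_dim = dim(mask$mask),
            gate = c(min_area, max_area))
}

#' Cohort-level OLS statistics
#'
#' Summarizes extracted lacuna sections over the evaluated bone area, taken
#' as mineralized area plus total lacunar area (the sectioned bone tissue
#' including its voids).
#'
#' @param records an `ols_records` data.frame from [extract_ols()].
#' @param mask the `mineral_mask` the records were extracted from.
#' @param roi optional [roi_spec()] delimiting the evaluated bone area.
#' @return object of class `ols_summary`: `ols_porosity` (percent of
#'   evaluated bone area occupied by lacunae), `ols_density` (lacunae per
#'   mm^2), `median_area` (um^2), `median_perimeter` (um), `n_lacunae`,
#'   `evaluated_area_um2`. Medians are `NA` when no lacunae were found.
#' @export
ols_summary <- function(records, mask, roi = NULL) {
  stopifnot(inherits(records, "ols_records"), inherits(mask, "mineral_mask"))
  if (!identical(attr(records, "mask_dim"), dim(mask$mask)) ||
      !isTRUE(all.equal(attr(records, "pixel_size"), mask$pixel_size)))
    oq_stop("records were not extracted from this mask", "oq_provenance_error")
  m <- mask$mask
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "roi_spec"))
    m <- m & roi$mask
  }
  mineral_area <- sum(m) * mask$pixel_size^2
  lac_area <- sum(records$area_um2)
  evaluated <- mineral_area + lac_area
  n <- nrow(records)
  structure(list(
    ols_porosity = if (n) 100 * lac_area / evaluated else 0,
    ols_density = if (n) n / (evaluated / 1e6) else 0,
    median_area = if (n) stats::median(records$area_um2) else NA_real_,
    median_perimeter = if (n) stats::median(records$perimeter_um) else NA_real_,
    n_lacunae = n,
    evaluated_area_um2 = evaluated),
    class = "ols_summary")
}

#' @export
print.ols_summary <- function(x, ...) {
  cat(sprintf(
    "OLS: n = %d, porosity %.2f%%, density %.0f /mm^2, median area %.1f um^2, median perimeter %.1f um\n",
    x$n_lacunae, x$ols_porosity, x$ols_density, x$median_area,
    x$median_perimeter))
  invisible(x)
}

#' Percentage of empty osteocyte lacunae
#'
#' Ratio statistic for upstream manual counts from decalcified histology:
#' lacunae without a preserved nucleus over all counted lacunae.
#'
#' @param n_empty count of empty lacunae.
#' @param n_total total counted lacunae.
#' @return percentage(s) of empty lacunae.
#' @export
empty_fraction <- function(n_empty, n_total) {
  if (any(!is.finite(n_total)) || any(n_total <= 0))
    oq_stop("n_total must be positive", "oq_empty_input_error")
  if (any(n_empty < 0) || any(n_empty > n_total))
    oq_stop("need 0 <= n_empty <= n_total", "oq_domain_error")
  100 * n_empty / n_total
}
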