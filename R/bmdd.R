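#' Bone mineralization density distribution (BMDD)
#'
#' The BMDD is the frequency histogram of calcium content over mineralized
#' bone pixels, expressed in percent of bone area per bin. Bins are
#' half-open `[lo, lo + bin_width)`, aligned so the first bin starts at
#' 0 wt\%Ca, and every curve is kept on the full fixed grid up to 45 wt\%Ca
#' so that curves from different samples share identical binning.
#'
#' @param camap a [ca_map()].
#' @param region optional [roi_spec()] restricting the histogram; `NULL`
#'   uses the whole map.
#' @param threshold mineralized/unmineralized boundary in wt\%Ca; only
#'   pixels with Ca >= threshold contribute.
#' @param bin_width histogram bin width in wt\%Ca. The default 0.17 equals
#'   one canonical gray-level step of the calibration, i.e. the native
#'   resolution of the calcium measurement.
#' @return an object of class `bmdd_curve` with `bin_centers` (wt\%Ca),
#'   `frequencies` (percent of bone area, summing to 100), `bin_width`,
#'   and `n_pixels`.
#' @export
compute_bmdd <- function(camap, region = NULL, threshold = 5.2,
                         bin_width = 0.17) {
  stopifnot(inherits(camap, "ca_map"), threshold >= 0, bin_width > 0)
  v <- camap$values
  if (!is.null(region)) {
    stopifnot(inherits(region, "roi_spec"))
    if (!identical(dim(region$mask), dim(v)))
      oq_stop("region geometry does not match the map", "oq_domain_error")
    v <- v[region$mask]
  }
  v <- v[!is.na(v)]
  v <- v[v >= threshold]
  if (!length(v))
    oq_stop("no mineralized pixels in region", "oq_empty_region_error")
  n_bins <- ceiling(45 / bin_width)
  # epsilon guards the half-open binning for values that sit exactly on a
  # bin edge up to floating-point error (quantized gray levels do)
  idx <- pmin(floor(v / bin_width + 1e-9), n_bins - 1) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  bmdd_curve(bin_centers = (seq_len(n_bins) - 0.5) * bin_width,
             frequencies = 100 * counts / length(v),
             bin_width = bin_width,
             n_pixels = length(v))
}

#' BMDD curve constructor
#' @param bin_centers uniformly spaced bin centers, wt\%Ca.
#' @param frequencies percent of bone area per bin.
#' @param bin_width bin width, wt\%Ca.
#' @param n_pixels number of contributing pixels.
#' @return object of class `bmdd_curve`.
#' @export
bmdd_curve <- function(bin_centers, frequencies, bin_width, n_pixels) {
  stopifnot(length(bin_centers) == length(frequencies), bin_width > 0,
            all(frequencies >= 0))
  if (length(bin_centers) > 1) {
    sp <- diff(bin_centers)
    if (max(abs(sp - bin_width)) > 1e-9 * bin_width)
      oq_stop("bin spacing must be constant and equal to bin_width",
              "oq_binning_error")
  }
  if (n_pixels > 0 && abs(sum(frequencies) - 100) > 1e-9)
    oq_stop("frequencies must sum to 100", "oq_domain_error")
  structure(list(bin_centers = bin_centers, frequencies = frequencies,
                 bin_width = bin_width, n_pixels = n_pixels),
            class = "bmdd_curve")
}

same_binning <- function(a, b) {
  length(a$bin_centers) == length(b$bin_centers) &&
    abs(a$bin_width - b$bin_width) < 1e-9 &&
    max(abs(a$bin_centers - b$bin_centers)) < 1e-9
}

#' Scalar BMDD descriptors: CaMean, CaPeak, CaWidth
#'
#' CaMean is the frequency-weighted mean calcium concentration; CaPeak the
#' position of the histogram maximum (exact ties resolved as the arithmetic
#' mean of the tied bin centers); CaWidth the full width at half the peak
#' frequency, linearly interpolated at the outermost half-maximum crossings
#' around the global peak.
#'
#' @param curve a [bmdd_curve()].
#' @return list of class `bmdd_params` with `ca_mean`, `ca_peak`, `ca_width`
#'   (all wt\%Ca).
#' @export
bmdd_params <- function(curve) {
  stopifnot(inherits(curve, "bmdd_curve"))
  f <- curve$frequencies
  x <- curve$bin_centers
  w <- curve$bin_width
  if (all(f == 0))
    oq_stop("all-zero BMDD curve", "oq_empty_curve_error")
  ca_mean <- sum(f * x) / sum(f)
  fmax <- max(f)
  tied <- which(abs(f - fmax) <= 1e-12 * fmax)
  ca_peak <- mean(x[tied])
  # FWHM: outermost crossings of half maximum, scanned from the curve ends
  h <- fmax / 2
  i_left <- which(f >= h)[1]
  i_right <- rev(which(f >= h))[1]
  x_left <- if (i_left == 1L) x[1] - w / 2 else
    x[i_left - 1] + w * (h - f[i_left - 1]) / (f[i_left] - f[i_left - 1])
  x_right <- if (i_right == length(f)) x[length(f)] + w / 2 else
    x[i_right] + w * (f[i_right] - h) / (f[i_right] - f[i_right + 1])
  structure(list(ca_mean = ca_mean, ca_peak = ca_peak,
                 ca_width = max(x_right - x_left, w)),
            class = "bmdd_params")
}

# cumulative percent of area strictly below `xq`, partial bins apportioned
# linearly within the bin
curve_cdf <- function(curve, xq) {
  f <- curve$frequencies
  lo <- curve$bin_centers - curve$bin_width / 2
  hi <- curve$bin_centers + curve$bin_width / 2
  vapply(xq, function(x) {
    if (x <= lo[1]) return(0)
    if (x >= hi[length(hi)]) return(sum(f))
    j <- findInterval(x, lo)  # bin containing x
    sum(f[seq_len(j - 1)]) + f[j] * (x - lo[j]) / curve$bin_width
  }, numeric(1))
}

# inverse of curve_cdf: calcium value below which `q` percent of area lies
curve_quantile <- function(curve, q) {
  f <- curve$frequencies
  lo <- curve$bin_centers - curve$bin_width / 2
  cs <- cumsum(f)
  vapply(q, function(p) {
    j <- which(cs >= p - 1e-12)[1]
    prev <- if (j == 1L) 0 else cs[j - 1]
    lo[j] + curve$bin_width * (p - prev) / f[j]
  }, numeric(1))
}

#' Pool BMDD curves into a reference and extract its 5th/95th percentiles
#'
#' The pooled curve is the unweighted mean of the input frequencies
#' (each animal counts equally regardless of bone area), renormalized to
#' 100\%. The percentiles are obtained by linear interpolation on the pooled
#' cumulative distribution and anchor the CaLow/CaHigh descriptors of
#' [ca_low_high()]. The study design uses the wild-type metaphyseal curves
#' of each age group as this reference.
#'
#' @param curves list of [bmdd_curve()] objects with identical binning.
#' @return object of class `reference_bmdd` with `pooled_curve`, `p5`, `p95`.
#' @export
reference_bmdd <- function(curves) {
  stopifnot(length(curves) >= 1)
  lapply(curves, function(cv) stopifnot(inherits(cv, "bmdd_curve")))
  for (cv in curves[-1])
    if (!same_binning(curves[[1]], cv))
      oq_stop("curves have mismatched binning", "oq_binning_error")
  fmat <- vapply(curves, `[[`, numeric(length(curves[[1]]$frequencies)),
                 "frequencies")
  f <- rowMeans(fmat)
  f <- 100 * f / sum(f)
  pooled <- bmdd_curve(curves[[1]]$bin_centers, f, curves[[1]]$bin_width,
                       n_pixels = sum(vapply(curves, `[[`, 0, "n_pixels")))
  p <- curve_quantile(pooled, c(5, 95))
  structure(list(pooled_curve = pooled, p5 = p[1], p95 = p[2]),
            class = "reference_bmdd")
}

#' CaLow and CaHigh against a reference BMDD
#'
#' CaLow is the percentage of mineralized bone area with calcium
#' concentration below the 5th percentile of the reference distribution,
#' CaHigh the percentage above its 95th percentile; partial bins are
#' apportioned linearly.
#'
#' @param curve a [bmdd_curve()].
#' @param ref a [reference_bmdd()] with the same binning.
#' @return named numeric vector `c(ca_low, ca_high)`, percent of bone area.
#' @export
ca_low_high <- function(curve, ref) {
  stopifnot(inherits(curve, "bmdd_curve"), inherits(ref, "reference_bmdd"))
  if (!same_binning(curve, ref$pooled_curve))
    oq_stop("curve binning does not match the reference", "oq_binning_error")
  c(ca_low = curve_cdf(curve, ref$p5),
    ca_high = sum(curve$frequencies) - curve_cdf(curve, ref$p95))
}

#' Full five-parameter BMDD description
#' @param curve a [bmdd_curve()].
#' @param ref a [reference_bmdd()] for CaLow/CaHigh.
#' @return one-row data.frame: ca_mean, ca_peak, ca_width, ca_low, ca_high.
#' @export
bmdd_all_params <- function(curve, ref) {
  p <- bmdd_params(curve)
  lh <- ca_low_high(curve, ref)
  data.frame(ca_mean = p$ca_mean, ca_peak = p$ca_peak, ca_width = p$ca_width,
             ca_low = unname(lh["ca_low"]), ca_high = unname(lh["ca_high"]))
}

#' @export
print.bmdd_curve <- function(x, ...) {
  nz <- which(x$frequencies > 0)
  cat(sprintf("BMDD: %d px, bin %.3g wt%%Ca, support %.2f-%.2f wt%%Ca\n",
              x$n_pixels, x$bin_width,
              x$bin_centers[min(nz)], x$bin_centers[max(nz)]))
  invisible(x)
}

#' @export
print.bmdd_params <- function(x, ...) {
  cat(sprintf("CaMean %.2f  CaPeak %.2f  CaWidth %.2f (wt%%Ca)\n",
              x$ca_mean, x$ca_peak, x$ca_width))
  invisible(x)
}

#' Plot a BMDD curve
#' @param x a [bmdd_curve()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.bmdd_curve <- function(x, ...) {
  nz <- which(x$frequencies > 0)
  if (!length(nz)) nz <- seq_along(x$frequencies)
  rng <- range(nz) + c(-3, 3)
  rng <- pmax(pmin(rng, length(x$frequencies)), 1)
  idx <- rng[1]:rng[2]
  graphics::plot(x$bin_centers[idx], x$frequencies[idx], type = "s",
                 xlab = "Ca content (wt%)", ylab = "% of bone area", ...)
  invisible(x)
}
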