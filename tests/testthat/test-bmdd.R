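test_that("histograms of degenerate inputs behave as defined", {
  cm <- camap_of(matrix(22.1, 10, 10))
  cv <- compute_bmdd(cm)
  expect_equal(sum(cv$frequencies), 100)
  expect_equal(sum(cv$frequencies > 0), 1)
  expect_equal(cv$frequencies[findInterval(22.1, cv$bin_centers - 0.085)], 100)
  # symmetric two-point input: two bins at 50% each
  cm2 <- camap_of(matrix(rep(c(20, 24), each = 50), 10, 10))
  cv2 <- compute_bmdd(cm2)
  expect_equal(sort(cv2$frequencies[cv2$frequencies > 0]), c(50, 50))
  # histogram ignores spatial arrangement
  set.seed(3)
  v <- matrix(runif(400, 6, 30), 20, 20)
  vs <- matrix(sample(v), 20, 20)
  expect_equal(compute_bmdd(camap_of(v))$frequencies,
               compute_bmdd(camap_of(vs))$frequencies)
  # all pixels below threshold
  expect_error(compute_bmdd(camap_of(matrix(1, 5, 5))),
               class = "oq_empty_region_error")
})

test_that("bmdd curves sum to 100 and keep constant bin spacing", {
  set.seed(9)
  for (bw in c(0.17, 0.5)) {
    cv <- compute_bmdd(camap_of(matrix(runif(1e4, 6, 40), 100, 100)),
                       bin_width = bw)
    expect_equal(sum(cv$frequencies), 100, tolerance = 1e-9)
    expect_true(all(abs(diff(cv$bin_centers) - bw) < 1e-9))
    expect_true(all(cv$frequencies >= 0))
  }
})

test_that("CaMean, CaPeak and CaWidth match their definitions", {
  mk <- function(f, bw = 1, start = 0.5)
    bmdd_curve(seq(start, by = bw, length.out = length(f)),
               100 * f / sum(f), bw, n_pixels = 1000)
  # two equal bins -> mean is the midpoint
  cv <- mk(c(1, 0, 0, 0, 1), bw = 1, start = 20)  # centers 20..24
  p <- bmdd_params(cv)
  expect_equal(p$ca_mean, 22)
  expect_equal(p$ca_peak, 22)  # tie between 20 and 24 -> mean of tied centers
  # single bin: width collapses to one bin width
  expect_equal(bmdd_params(mk(c(0, 1, 0)))$ca_width, 1)
  expect_error(bmdd_params(mk(c(1, 1)) |> (\(x) {
    x$frequencies[] <- 0; x })()), class = "oq_empty_curve_error")
})

test_that("CaWidth of a Gaussian sample approaches 2.3548 sigma", {
  set.seed(42)
  v <- rnorm(1e6, 25, 1.5)
  cv <- compute_bmdd(camap_of(matrix(v, 1000, 1000)))
  p <- bmdd_params(cv)
  expect_lt(abs(p$ca_mean - 25), 0.05)
  # dense numeric oracle on the same sample: FWHM from a fine kde-free
  # histogram, against the closed form 2*sqrt(2 log 2) * sigma
  expect_equal(p$ca_width, 2.3548 * 1.5, tolerance = 0.03)
  h <- hist(v, breaks = seq(15, 35, by = 0.05), plot = FALSE)
  half <- max(h$counts) / 2
  crossings <- range(which(h$counts >= half))
  oracle <- h$mids[crossings[2]] - h$mids[crossings[1]]
  expect_equal(p$ca_width, oracle, tolerance = 0.05)
})

test_that("reference percentiles match closed forms and the cumulative oracle", {
  # uniform curve over [20, 30): 20 bins of width 0.5, 5% each
  centers <- seq(20.25, by = 0.5, length.out = 20)
  uni <- bmdd_curve(centers, rep(5, 20), 0.5, 1000)
  ref <- reference_bmdd(list(uni))
  expect_equal(ref$p5, 20.5, tolerance = 1e-9)
  expect_equal(ref$p95, 29.5, tolerance = 1e-9)
  expect_equal(oracle_cdf(uni, ref$p5), 5, tolerance = 1e-9)
  # pooling two identical curves is idempotent
  ref2 <- reference_bmdd(list(uni, uni))
  expect_equal(ref2$pooled_curve$frequencies, uni$frequencies)
  # disjoint support: p5 inside the lower curve, p95 inside the upper
  lowc <- bmdd_curve(centers, c(rep(10, 10), rep(0, 10)), 0.5, 500)
  highc <- bmdd_curve(centers, c(rep(0, 10), rep(10, 10)), 0.5, 500)
  ref3 <- reference_bmdd(list(lowc, highc))
  expect_lt(ref3$p5, 25)
  expect_gt(ref3$p95, 25)
  expect_equal(oracle_cdf(ref3$pooled_curve, ref3$p5), 5, tolerance = 1e-9)
  expect_equal(oracle_cdf(ref3$pooled_curve, ref3$p95), 95, tolerance = 1e-9)
  expect_error(reference_bmdd(list(uni, bmdd_curve(centers + 1, rep(5, 20),
                                                   0.5, 10))),
               class = "oq_binning_error")
})

test_that("CaLow/CaHigh follow the reference percentiles", {
  centers <- seq(20.25, by = 0.5, length.out = 20)
  uni <- bmdd_curve(centers, rep(5, 20), 0.5, 1000)
  ref <- reference_bmdd(list(uni))
  lh <- ca_low_high(uni, ref)  # a curve against a reference built from itself
  expect_equal(unname(lh), c(5, 5), tolerance = 1e-9)
  # curve with all mass below the reference p5 (same binning, first bin)
  below <- bmdd_curve(centers, c(100, rep(0, 19)), 0.5, 100)
  lh2 <- ca_low_high(below, ref)
  expect_equal(unname(lh2), c(100, 0))
  # shifting a curve up by one bin lowers CaLow and raises CaHigh,
  # by exactly the amounts the cumulative oracle predicts
  shifted <- bmdd_curve(centers, c(0, rep(5, 19)) * 100 / 95, 0.5, 1000)
  lh3 <- ca_low_high(shifted, ref)
  expect_lt(lh3["ca_low"], lh["ca_low"])
  expect_gt(lh3["ca_high"], lh["ca_high"])
  expect_equal(unname(lh3["ca_low"]), oracle_cdf(shifted, ref$p5),
               tolerance = 1e-9)
  expect_equal(unname(lh3["ca_high"]),
               100 - oracle_cdf(shifted, ref$p95), tolerance = 1e-9)
})

test_that("adding a constant shifts CaMean/CaPeak and preserves CaWidth", {
  set.seed(7)
  v <- matrix(rnorm(4e4, 22, 1.2), 200, 200)
  shift <- 3 * 0.17  # whole bins, so discretization cannot leak
  p1 <- bmdd_params(compute_bmdd(camap_of(v)))
  p2 <- bmdd_params(compute_bmdd(camap_of(v + shift)))
  expect_lt(abs((p2$ca_mean - p1$ca_mean) - shift), 0.17)
  expect_lt(abs((p2$ca_peak - p1$ca_peak) - shift), 0.17)
  expect_lt(abs(p2$ca_width - p1$ca_width), 0.17)
})

test_that("quantized gray-level maps do not alias across bin edges", {
  # gray levels map to exact multiples of 0.17; every level must fill its
  # own bin (no empty bins inside the support, no double-height spikes)
  m <- fit_calibration(25, 225)
  g <- matrix(rep(100:140, each = 10), 10, 41)
  cv <- compute_bmdd(apply_calibration(g, m))
  nz <- which(cv$frequencies > 0)
  expect_equal(length(nz), 41)
  expect_true(all(diff(nz) == 1))
})
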