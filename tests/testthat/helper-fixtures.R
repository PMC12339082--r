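# shared fixtures, all built in code

# calcium map straight from a value matrix
camap_of <- function(values, pixel_size = 0.88) {
  ca_map(values, pixel_size = pixel_size)
}

# binary mask wrapped with a given pixel size
mask_of <- function(m, pixel_size = 0.88) {
  mineral_mask(m, pixel_size = pixel_size)
}

# vertical stripe phantom: alternating `w` px off / `w` px on, starting
# with an off stripe so no on-stripe touches the raster border (border
# contact reads as a continuing structure in the thickness field)
stripe_mask <- function(nr = 600, nc = 600, w = 50) {
  on <- ((seq_len(nc) - 1) %/% w) %% 2 == 1
  matrix(rep(on, each = nr), nr, nc)
}

# scaled-down generator configuration for fast unit tests
small_config <- function(...) {
  synthetic_config(width_um = 400, cortex_um = 70, margin_um = 40,
                   epiphysis_um = 200, growth_plate_um = 150,
                   primary_um = 220, secondary_um = 300, tail_um = 40, ...)
}

# matching pipeline configuration (band depths equal the generator zones)
small_run_config <- function(...) {
  run_config(primary_um = 220, secondary_um = 300, ...)
}

# brute-force local thickness straight from the definition: for every
# foreground pixel the diameter of the largest disc that is fully inside
# the phase and contains the pixel; independent of the EDT implementation
brute_local_thickness <- function(mask) {
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  if (!nrow(fg)) return(out)
  # radius at each candidate centre: distance to the nearest background px
  r_c <- if (nrow(bg)) {
    apply(fg, 1, function(p)
      sqrt(min((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2)))
  } else rep(sqrt(nrow(mask)^2 + ncol(mask)^2), nrow(fg))
  for (i in seq_len(nrow(fg))) {
    d <- sqrt((fg[, 1] - fg[i, 1])^2 + (fg[, 2] - fg[i, 2])^2)
    covered <- d <= r_c - 0.5
    out[fg[i, 1], fg[i, 2]] <- max(2 * r_c[covered] - 1)
  }
  out
}

# per-column growth-plate scan, independent of the band-profile machinery:
# thickness of the unmineralized run between the two mineralized blocks
brute_gp_scan <- function(mask, pixel_size = 0.88) {
  apply(mask, 2, function(col) {
    on <- which(col)
    if (!length(on)) return(NA_real_)
    gaps <- which(diff(on) > 1)
    if (!length(gaps)) return(NA_real_)
    k <- gaps[which.max(diff(on)[gaps])]
    (on[k + 1] - on[k] - 1) * pixel_size
  })
}

# cumulative percentage of a curve strictly below x, by fine-grained
# numerical accumulation (oracle for curve_cdf / percentiles)
oracle_cdf <- function(curve, x) {
  lo <- curve$bin_centers - curve$bin_width / 2
  hi <- curve$bin_centers + curve$bin_width / 2
  sum(curve$frequencies * pmin(pmax((x - lo) / (hi - lo), 0), 1))
}
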