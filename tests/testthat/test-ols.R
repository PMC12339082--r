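# rasterize an ellipse void into a mineral plate
carve_ellipse <- function(m, cy, cx, a_um, b_um, theta = 0, ps = 0.88) {
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    dx <- (j - cx) * ps; dy <- (i - cy) * ps
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    if ((u / a_um)^2 + (v / b_um)^2 <= 1) m[i, j] <- FALSE
  }
  m
}

test_that("an enclosed ellipse is extracted with its rasterized area", {
  m <- matrix(TRUE, 60, 60)
  m <- carve_ellipse(m, 30.37, 30.23, 3, 2)
  recs <- extract_ols(mask_of(m))
  expect_equal(nrow(recs), 1)
  # pixel-count oracle on the same rasterization
  expect_equal(recs$area_um2, sum(!m) * 0.88^2)
  # and the continuous area within 10%
  expect_lt(abs(recs$area_um2 - pi * 3 * 2) / (pi * 6), 0.1)
  expect_lt(abs(recs$cx - 30.23), 0.5)
  expect_lt(abs(recs$cy - 30.37), 0.5)
})

test_that("size gate and enclosure rules are enforced", {
  m <- matrix(TRUE, 80, 80)
  m[10:11, 10:11] <- FALSE        # 4 px = 3.10 um^2, below the 5 um^2 gate
  m[40:45, 40:48] <- FALSE        # 54 px = 41.8 um^2, in gate
  m[1:6, 60:67] <- FALSE          # touches the image border: excluded
  recs <- extract_ols(mask_of(m))
  expect_equal(nrow(recs), 1)
  expect_equal(recs$area_um2, 54 * 0.88^2)
  # inclusive bounds: a hole of exactly min_area survives
  m2 <- matrix(TRUE, 30, 30)
  m2[10:12, 10:12] <- FALSE       # 9 px
  ps <- sqrt(5 / 9)               # makes the area exactly 5 um^2
  expect_equal(nrow(extract_ols(mask_of(m2, pixel_size = ps))), 1)
  # 8-adjacency to off-sample pixels disqualifies
  off <- matrix(FALSE, 80, 80); off[46, 49] <- TRUE  # diagonal neighbour
  m3 <- mineral_mask(m, pixel_size = 0.88, off_sample = off)
  expect_equal(nrow(extract_ols(m3)), 0)
})

test_that("voids use 8-connectivity", {
  m <- matrix(TRUE, 40, 40)
  # two 3x3 holes joined only diagonally: one component of 18 px
  m[10:12, 10:12] <- FALSE
  m[13:15, 13:15] <- FALSE
  recs <- extract_ols(mask_of(m, pixel_size = 1))
  expect_equal(nrow(recs), 1)
  expect_equal(recs$area_um2, 18)
})

test_that("gate widening/narrowing changes counts monotonically and shifts preserve records", {
  set.seed(33)
  img <- generate_bone_image(small_config(), seed = 8, full_truth = TRUE)
  msk <- mineral_mask(img$truth$structure_mask,
                      pixel_size = img$meta$pixel_size)
  r_full <- extract_ols(msk, 5, 200)
  r_wide <- extract_ols(msk, 5, 400)
  r_low <- extract_ols(msk, 12, 200)
  expect_gte(nrow(r_wide), nrow(r_full))
  expect_lte(nrow(r_low), nrow(r_full))
  expect_true(all(r_low$area_um2 >= 12))
  # translation by whole pixels preserves areas and perimeters
  sh <- rbind(msk$mask[-(1:3), ], msk$mask[1:3, ])
  r_sh <- extract_ols(mineral_mask(sh, pixel_size = msk$pixel_size), 5, 200)
  expect_equal(sort(r_sh$area_um2), sort(r_full$area_um2))
  expect_equal(sort(r_sh$perimeter_um), sort(r_full$perimeter_um),
               tolerance = 1e-9)
})

test_that("planted lacunae are recovered exactly with matching areas", {
  img <- generate_bone_image(small_config(), seed = 14, full_truth = TRUE)
  camap <- apply_calibration(img$raw, fit_calibration(25, 225))
  recs <- extract_ols(make_mineral_mask(camap))
  truth <- img$truth$lacunae
  in_gate <- truth[truth$area_um2 >= 5 & truth$area_um2 <= 200, ]
  expect_equal(nrow(recs), nrow(in_gate))
  # match by centroid, compare rasterized areas within 10%
  o <- order(recs$cy, recs$cx); ot <- order(in_gate$cy, in_gate$cx)
  expect_equal(recs$area_um2[o], in_gate$area_um2[ot], tolerance = 0.1)
  # Crofton perimeters respect the isoperimetric bound within pixelation
  expect_true(all(recs$perimeter_um^2 >= 0.95 * 4 * pi * recs$area_um2))
})

test_that("Crofton perimeter converges to the circumference of a disc", {
  m <- matrix(TRUE, 140, 140)
  m[sqrt(outer((1:140 - 70)^2, (1:140 - 70)^2, "+")) <= 25] <- FALSE
  recs <- extract_ols(mask_of(m, pixel_size = 1), 100, 1e5)
  expect_lt(abs(recs$perimeter_um - 2 * pi * 25) / (2 * pi * 25), 0.03)
})

test_that("summary statistics follow their definitions", {
  # one 20 um^2 lacuna in 0.01 mm^2 evaluated bone (pixel size 1 um)
  m <- matrix(TRUE, 100, 100)
  m[50:53, 50:54] <- FALSE  # 20 px = 20 um^2
  msk <- mask_of(m, pixel_size = 1)
  recs <- extract_ols(msk, 5, 200)
  s <- ols_summary(recs, msk)
  expect_equal(s$evaluated_area_um2, 1e4)
  expect_equal(s$ols_density, 100)      # 1 per 0.01 mm^2
  expect_equal(s$ols_porosity, 0.2)
  # zero lacunae
  s0 <- ols_summary(extract_ols(mask_of(matrix(TRUE, 20, 20))),
                    mask_of(matrix(TRUE, 20, 20)))
  expect_equal(s0$n_lacunae, 0)
  expect_equal(s0$ols_porosity, 0)
  expect_equal(s0$ols_density, 0)
  expect_true(is.na(s0$median_area))
  # even-n median convention
  m2 <- matrix(TRUE, 60, 120)
  m2[20:24, 20:21] <- FALSE   # 10 px
  m2[40:45, 80:84] <- FALSE   # 30 px
  msk2 <- mask_of(m2, pixel_size = 1)
  s2 <- ols_summary(extract_ols(msk2, 5, 200), msk2)
  expect_equal(s2$median_area, 20)
  # provenance guard
  expect_error(ols_summary(extract_ols(msk2, 5, 200), msk),
               class = "oq_provenance_error")
})

test_that("mineral, lacunar and open void fractions partition the region", {
  img <- generate_bone_image(small_config(), seed = 4, full_truth = TRUE)
  msk <- mineral_mask(img$truth$structure_mask,
                      pixel_size = img$meta$pixel_size)
  recs <- extract_ols(msk, 5, 200)
  a <- msk$pixel_size^2
  mineral <- sum(msk$mask) * a
  lacunar <- sum(recs$area_um2)
  total <- length(msk$mask) * a
  open_void <- total - mineral - lacunar
  expect_gte(open_void, 0)
  expect_equal((mineral + lacunar + open_void) / total, 1)
})

test_that("empty-lacuna percentages are guarded ratio statistics", {
  expect_equal(empty_fraction(3, 10), 30)
  expect_equal(empty_fraction(0, 1400), 0)
  expect_equal(empty_fraction(c(1, 2), c(4, 8)), c(25, 25))
  expect_error(empty_fraction(1, 0), class = "oq_empty_input_error")
  expect_error(empty_fraction(5, 4), class = "oq_domain_error")
})
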