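test_that("generation is deterministic and leaves the caller's RNG alone", {
  cfg <- small_config()
  a <- generate_bone_image(cfg, seed = 5)
  set.seed(1); before <- runif(3)
  b <- generate_bone_image(cfg, seed = 5)
  set.seed(1); after <- runif(3)
  expect_identical(a$raw, b$raw)
  expect_identical(a$truth$lacunae, b$truth$lacunae)
  expect_identical(before, after)
  expect_false(identical(a$raw, generate_bone_image(cfg, seed = 6)$raw))
})

test_that("noise-free zones sit at the inverse-calibration gray levels", {
  cfg <- small_config(noise_sd_gl = 0,
                      ca = list(cortex = c(mean = 24, sd = 0),
                                epiphysis = c(mean = 22.5, sd = 0),
                                metaphysis = c(mean = 21, sd = 0),
                                background = c(mean = 0, sd = 0)),
                      lacunae = list(density_mm2 = 0, meanlog = 0,
                                     sdlog = 0.1, aspect = c(1.6, 3)))
  img <- generate_bone_image(cfg, seed = 2, full_truth = TRUE)
  model <- fit_calibration(25, 225)
  S <- img$truth$structure_mask; Z <- img$truth$zone
  expect_equal(unique(as.vector(img$raw[S & Z == 1])),
               round(gray_from_ca(model, 24)))
  expect_equal(unique(as.vector(img$raw[S & Z == 2])),
               round(gray_from_ca(model, 22.5)))
  expect_equal(unique(as.vector(img$raw[!S])), round(gray_from_ca(model, 0)))
})

test_that("planted growth-plate band and textures match the config", {
  cfg <- small_config()
  img <- generate_bone_image(cfg, seed = 3, full_truth = TRUE)
  ps <- cfg$pixel_size
  expect_equal(unique(img$truth$gp_thickness_um), img$truth$gp_height_px * ps)
  expect_equal(img$truth$gp_height_px, round(150 / ps))
  # achieved area fractions track the targets closely (rasterization only)
  expect_lt(abs(img$truth$achieved_bvtv[["primary"]] - 35), 1)
  expect_lt(abs(img$truth$achieved_bvtv[["secondary"]] - 20), 1)
  # zone calcium ordering is planted
  expect_true(cfg$ca$cortex["mean"] >= cfg$ca$epiphysis["mean"])
})

test_that("infeasible geometries raise config errors", {
  expect_error(synthetic_config(width_um = 220, cortex_um = 100),
               class = "oq_config_error")
  expect_error(synthetic_config(growth_plate_um = 1),
               class = "oq_config_error")
  expect_error(
    synthetic_config(ca = list(cortex = c(mean = 20, sd = 1),
                               epiphysis = c(mean = 22, sd = 1),
                               metaphysis = c(mean = 21, sd = 1),
                               background = c(mean = 1, sd = 0.5))),
    class = "oq_config_error")
  expect_error(generate_cohort(small_config(effect = list(growth_plate = -1)),
                               2, 2, seed = 1),
               class = "oq_config_error")
})

test_that("the full pipeline recovers planted truth on a noise-free image", {
  cfg <- small_config(noise_sd_gl = 0)
  img <- generate_bone_image(cfg, seed = 9, full_truth = TRUE)
  rec <- run_sample(img, config = small_run_config())
  # BV/TV within 1 absolute percent of the planted fraction
  expect_lt(abs(rec$histo$bv_tv[rec$histo$region == "primary"] -
                  img$truth$achieved_bvtv[["primary"]]), 1)
  expect_lt(abs(rec$histo$bv_tv[rec$histo$region == "secondary"] -
                  img$truth$achieved_bvtv[["secondary"]]), 1)
  # growth plate within one pixel
  expect_lt(abs(rec$gp$mean_thickness - img$truth$gp_height_px * 0.88), 0.88)
  # lacuna count exact
  truth <- img$truth$lacunae
  expect_equal(rec$ols$n_lacunae,
               sum(truth$area_um2 >= 5 & truth$area_um2 <= 200))
  # zone CaMean within one bin width
  expect_lt(abs(rec$bmdd$ca_mean[rec$bmdd$site == "Ct"] - 24), 0.17)
  expect_lt(abs(rec$bmdd$ca_mean[rec$bmdd$site == "Ms"] - 21), 0.17)
})

test_that("cohorts are deterministic, labelled, and respond to the effect profile", {
  cfg <- small_config()
  coh <- generate_cohort(cfg, 3, 4, age_group = "8W", seed = 6)
  coh2 <- generate_cohort(cfg, 3, 4, age_group = "8W", seed = 6)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(cohort_image(coh, 5)$raw, cohort_image(coh2, 5)$raw)
  expect_equal(table(coh$manifest$genotype),
               table(factor(c(rep("WT", 3), rep("MUT", 4)))))
  expect_true(all(c("M", "F") %in% coh$manifest$sex))
  # null profile: WT and MUT parameter draws come from the same distribution
  ones <- setNames(as.list(rep(1, 11)),
                   c(names(effect_profile("8W"))))
  null_coh <- generate_cohort(small_config(effect = ones), 30, 30, seed = 3)
  gp_planted <- vapply(null_coh$samples,
                       function(s) s$config$growth_plate_um, 0)
  g <- null_coh$manifest$genotype
  expect_equal(mean(gp_planted[g == "MUT"]) / mean(gp_planted[g == "WT"]), 1,
               tolerance = 0.03)
  # planted scaling with no variation: percent difference is exact
  det <- small_config(between_animal_cv = 0,
                      effect = list(growth_plate = 0.8))
  coh3 <- generate_cohort(det, 2, 2, seed = 4)
  gp3 <- vapply(coh3$samples, function(s) s$config$growth_plate_um, 0)
  expect_equal(100 * (mean(gp3[coh3$manifest$genotype == "MUT"]) /
                        mean(gp3[coh3$manifest$genotype == "WT"]) - 1), -20)
})

test_that("shipped effect profiles carry the study's group differences", {
  p8 <- effect_profile("8W")
  p15 <- effect_profile("15W")
  expect_equal(p8$growth_plate, 0.82)
  expect_equal(p15$growth_plate, 0.75)
  expect_equal(p8$bvtv_primary, 0.77)
  expect_equal(p15$bvtv_primary, 0.62)
  expect_equal(p8$bvtv_secondary, 0.64)
  expect_equal(p8$tbth_secondary, 0.79)
  expect_equal(p15$tbth_secondary, 0.76)
  expect_true(all(unlist(p8[c("ca_cortex", "ca_epiphysis",
                              "ca_metaphysis")]) == 1))
})

test_that("written cohorts round-trip through disk artifacts", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(small_config(), 1, 1, seed = 2, write_dir = dir)
  expect_true(all(file.exists(coh$manifest$path)))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(man$sample_id, coh$manifest$sample_id)
  img <- cohort_image(coh, 1)
  expect_identical(read_qbei_image(coh$manifest$path[1]), img$raw)
  tr <- jsonlite::read_json(file.path(dir, paste0(coh$manifest$sample_id[1],
                                                  "_truth.json")),
                            simplifyVector = TRUE)
  expect_equal(tr$gp_height_px, img$truth$gp_height_px)
})
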