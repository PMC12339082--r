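# Synthetic qBEI image and cohort generator with planted, recorded ground
# truth. The phantom emulates a longitudinal long-bone section: flanking
# cortical bands, an epiphyseal trabecular compartment, an unmineralized
# growth-plate band (resting + proliferative cartilage), and a metaphyseal
# compartment split into primary- and secondary-spongiosa texture bands.
# Thin mineralized seam plates border the growth plate on both sides (the
# tidemark / chondro-osseous junction), so the planted band thickness is
# exactly defined. Trabeculae are dashed rods of exact width, aligned with
# the bone axis; per-line stratified gap placement makes the achieved area
# fraction match the target to rasterization accuracy. Elliptical osteocyte
# lacunae are carved into the cortex. Calcium values are drawn per zone,
# mapped to gray levels through the inverse calibration, and detector noise
# is added last.

#' Configuration for the synthetic bone-section generator
#'
#' Defaults describe a wild-type mouse long-bone section at the working
#' resolution of the imaging pipeline (0.88 um/px). Per-zone calcium means
#' decrease from cortex to epiphysis to metaphysis, reflecting decreasing
#' tissue age.
#'
#' @param pixel_size micrometers per pixel.
#' @param width_um total section width.
#' @param margin_um unmineralized margin above and below the section.
#' @param cortex_um width of each flanking cortical band.
#' @param epiphysis_um,growth_plate_um,primary_um,secondary_um,tail_um zone
#'   extents along the bone axis, micrometers.
#' @param plate_um thickness of the mineralized seam plates bordering the
#'   growth plate.
#' @param ca per-zone calcium distribution parameters, each `c(mean, sd)`
#'   in wt\%Ca; `background` covers marrow/embedding and the growth plate.
#' @param trabecular per-band texture targets: `bvtv` (percent area
#'   fraction) and `tbth` (rod width, um) for `epiphysis`, `primary`,
#'   `secondary`.
#' @param rod_fill nominal along-rod fill fraction used to choose the rod
#'   line count.
#' @param dash_um nominal dash (trabecular segment) length.
#' @param lacunae lacuna field: `density_mm2`, log-normal section-area
#'   parameters `meanlog`/`sdlog` (um^2 scale), `aspect` range.
#' @param noise_sd_gl additive Gaussian detector noise, gray levels.
#' @param standards measured gray levels of the carbon and aluminum
#'   standards written into the image metadata.
#' @param calibration canonical calibration constants ([qbei_constants()]).
#' @param between_animal_cv between-animal coefficient of variation applied
#'   multiplicatively to zone and texture parameters when cohorts are drawn.
#' @param effect optional genotype effect profile (see [effect_profile()]);
#'   `NULL` means no genotype effect (all scalings 1).
#' @param enforce_zone_order require cortex >= epiphysis >= metaphysis
#'   calcium means.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(pixel_size = 0.88,
                             width_um = 1060,
                             margin_um = 50,
                             cortex_um = 100,
                             epiphysis_um = 320,
                             growth_plate_um = 150,
                             primary_um = 500,
                             secondary_um = 1000,
                             tail_um = 60,
                             plate_um = 3.5,
                             ca = list(cortex = c(mean = 24, sd = 1.3),
                                       epiphysis = c(mean = 22.5, sd = 1.3),
                                       metaphysis = c(mean = 21, sd = 1.3),
                                       background = c(mean = 1, sd = 0.5)),
                             trabecular = list(
                               epiphysis = list(bvtv = 30, tbth = 40),
                               primary = list(bvtv = 35, tbth = 30),
                               secondary = list(bvtv = 20, tbth = 45)),
                             rod_fill = 0.7,
                             dash_um = 250,
                             lacunae = list(density_mm2 = 600,
                                            meanlog = log(30), sdlog = 0.45,
                                            aspect = c(1.6, 3)),
                             noise_sd_gl = 3,
                             standards = c(carbon = 25, aluminum = 225),
                             calibration = qbei_constants(),
                             between_animal_cv = 0.03,
                             effect = NULL,
                             enforce_zone_order = TRUE) {
  cfg <- structure(as.list(environment()), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  ps <- cfg$pixel_size
  if (ps <= 0) oq_stop("pixel_size must be positive", "oq_config_error")
  for (z in c("cortex", "epiphysis", "metaphysis", "background"))
    if (cfg$ca[[z]]["sd"] < 0)
      oq_stop("calcium sds must be non-negative", "oq_config_error")
  if (cfg$enforce_zone_order) {
    mns <- vapply(cfg$ca[c("cortex", "epiphysis", "metaphysis")],
                  function(x) x[["mean"]], 0)
    if (is.unsorted(rev(mns)))
      oq_stop("zone calcium means must decrease cortex >= epiphysis >= metaphysis",
              "oq_config_error")
  }
  trab_w <- cfg$width_um - 2 * cfg$cortex_um
  if (trab_w < 100)
    oq_stop("trabecular compartment narrower than 100 um: geometry does not fit",
            "oq_config_error")
  for (nm in names(cfg$trabecular)) {
    tr <- cfg$trabecular[[nm]]
    if (tr$bvtv < 0 || tr$bvtv > 95 || tr$tbth <= 0)
      oq_stop(sprintf("invalid trabecular targets for %s band", nm),
              "oq_config_error")
  }
  zones_px <- round(c(cfg$epiphysis_um, cfg$growth_plate_um, cfg$primary_um,
                      cfg$secondary_um) / ps)
  if (any(zones_px < 4))
    oq_stop("zone extents too small for the pixel size", "oq_config_error")
  if (round(cfg$plate_um / ps) >= min(zones_px))
    oq_stop("seam plate thicker than a zone", "oq_config_error")
  if (!is.null(cfg$effect) &&
      any(unlist(cfg$effect[vapply(cfg$effect, is.numeric, TRUE)]) <= 0))
    oq_stop("effect scalings must be positive", "oq_config_error")
  invisible(cfg)
}

#' Shipped genotype effect profiles
#'
#' Multiplicative mutant/wild-type scalings applied by [generate_cohort()]
#' to growth-plate thickness, spongiosa area fractions and trabecular
#' widths, per age group. The shipped values are transcribed in
#' `extdata/effect_profiles.yaml` from the group differences measured in
#' the progeria (*Lmna* G609G) mouse cohorts this pipeline targets; code
#' carries no effect numbers.
#'
#' @param age_group profile name, `"8W"` or `"15W"`.
#' @param path optional alternative YAML file.
#' @return named list of scalings.
#' @export
effect_profile <- function(age_group = c("8W", "15W"), path = NULL) {
  age_group <- match.arg(age_group)
  path <- path %||% system.file("extdata", "effect_profiles.yaml",
                                package = "osteoquant")
  prof <- yaml::read_yaml(path)
  if (is.null(prof[[age_group]]))
    oq_stop(sprintf("no effect profile for age group '%s'", age_group),
            "oq_config_error")
  prof[[age_group]]
}

# Dashed-rod trabecular texture. Rod lines of exact width w_px run along
# the rows; each line is split into height cells and one gap of length
# (1 - lambda) * cell is placed uniformly inside every cell, so the covered
# fraction equals lambda per cell up to rasterization.
dashed_rods <- function(nrows, ncols, w_px, bvtv, fill = 0.7, dash_px = 284) {
  out <- matrix(FALSE, nrows, ncols)
  if (bvtv <= 0 || nrows < 1) return(out)
  w_px <- max(w_px, 1)
  cover <- ncols * bvtv / 100           # column budget of mineral
  m <- max(1L, as.integer(round(cover / (w_px * fill))))
  lambda <- cover / (m * w_px)
  while (lambda > 0.92) {
    m <- m + 1L
    lambda <- cover / (m * w_px)
  }
  spacing <- ncols / m
  centers <- spacing * (seq_len(m) - 0.5) +
    stats::runif(m, -0.15 * spacing, 0.15 * spacing)
  n_cells <- max(1L, as.integer(round(nrows / max(dash_px / lambda, 2))))
  bounds <- round(seq(0, nrows, length.out = n_cells + 1))
  for (xc in centers) {
    # per-rod width jitter: natural width variation, and it averages out
    # the odd/even pixel-count parity of the rasterized rod width
    wi <- max(2, w_px + stats::runif(1, -2, 2))
    j0 <- ceiling(xc - wi / 2 + 0.5)
    j1 <- ceiling(xc + wi / 2 + 0.5) - 1
    cols <- max(1, j0):min(ncols, j1)
    covered <- rep(TRUE, nrows)
    for (k in seq_len(n_cells)) {
      h <- bounds[k + 1] - bounds[k]
      gap <- (1 - lambda) * h
      u <- stats::runif(1, 0, h - gap)
      # snap gaps that would leave a dash fragment shorter than the rod
      # width to the cell boundary; coverage is unchanged, sub-width
      # fragments (which would depress the local thickness) are avoided
      if (u < w_px) u <- 0
      else if (h - (u + gap) < w_px) u <- h - gap
      u <- bounds[k] + u
      i0 <- ceiling(u + 0.5)
      i1 <- ceiling(u + gap + 0.5) - 1
      if (i1 >= i0) covered[max(1, i0):min(nrows, i1)] <- FALSE
    }
    out[covered, cols] <- TRUE
  }
  out
}

# carve elliptical lacunae into a cortical band; returns truth table
stamp_lacunae <- function(S, rows, cols, cfg) {
  ps <- cfg$pixel_size
  lac <- cfg$lacunae
  if (lac$density_mm2 <= 0)
    return(list(S = S, truth = NULL))
  cell_px <- max(8L, as.integer(ceiling(sqrt(1e6 / lac$density_mm2) / ps)))
  p_cell <- min(1, lac$density_mm2 * (cell_px * ps)^2 / 1e6)
  r0 <- rows[1]; c0 <- cols[1]
  nr_cells <- (rows[length(rows)] - r0 + 1) %/% cell_px
  nc_cells <- (cols[length(cols)] - c0 + 1) %/% cell_px
  rec <- list()
  for (ir in seq_len(nr_cells)) for (ic in seq_len(nc_cells)) {
    if (stats::runif(1) > p_cell) next
    lo_r <- r0 + (ir - 1L) * cell_px
    lo_c <- c0 + (ic - 1L) * cell_px
    area <- Inf
    while (area < 5 || area > 200)
      area <- stats::rlnorm(1, lac$meanlog, lac$sdlog)
    q <- stats::runif(1, lac$aspect[1], lac$aspect[2])
    a <- sqrt(area * q / pi); b <- a / q          # semi-axes, um
    th <- pi / 2 + stats::rnorm(1, 0, 0.2)        # long axis ~ bone axis
    # clearance from the cell boundary scales with this lacuna's own size,
    # so placements spread over the cell and neighbours keep >= 4 px apart
    rmax <- ceiling(a / ps) + 2
    jit <- cell_px - 2 * rmax
    if (jit < 1) next
    cy <- lo_r + rmax + stats::runif(1, 0, jit)
    cx <- lo_c + rmax + stats::runif(1, 0, jit)
    if (cx - rmax < cols[1] + 3 || cx + rmax > cols[length(cols)] - 3) next
    rad <- ceiling(a / ps) + 1
    ri <- max(1, floor(cy - rad)):min(nrow(S), ceiling(cy + rad))
    ci <- max(1, floor(cx - rad)):min(ncol(S), ceiling(cx + rad))
    dy <- (ri - cy) * ps
    dx <- (ci - cx) * ps
    u <- outer(dy, dx, function(y, x) x * cos(th) + y * sin(th))
    v <- outer(dy, dx, function(y, x) -x * sin(th) + y * cos(th))
    inside <- (u / a)^2 + (v / b)^2 <= 1
    if (!any(inside)) next
    S[ri, ci][inside] <- FALSE
    rec[[length(rec) + 1L]] <- data.frame(
      cy = cy, cx = cx, a_um = a, b_um = b, theta = th,
      area_px = sum(inside), area_um2 = sum(inside) * ps^2)
  }
  truth <- if (length(rec)) do.call(rbind, rec) else NULL
  list(S = S, truth = truth)
}

#' Generate one synthetic qBEI bone-section image
#'
#' Deterministic for a fixed `(config, seed)` pair. Ground truth reports
#' quantities of the rasterized image (achieved area fractions are pixel
#' counts, lacuna areas are rasterized pixel counts), not the continuous
#' parameters.
#'
#' @param config a [synthetic_config()]; mutant effect scalings, if any,
#'   must already be folded into the config (see [generate_cohort()]).
#' @param seed integer seed.
#' @param full_truth keep the zone-label raster and the pre-noise structure
#'   mask in the truth record (heavy; disable for cohort generation).
#' @return list of class `synthetic_bone_image`: `raw` (integer gray-level
#'   matrix), `truth`, `meta` (standards, pixel size).
#' @export
generate_bone_image <- function(config = synthetic_config(), seed = 1,
                                full_truth = TRUE) {
  validate_synthetic_config(config)
  with_seed(seed, generate_bone_image_impl(config, seed, full_truth))
}

generate_bone_image_impl <- function(cfg, seed, full_truth) {
  ps <- cfg$pixel_size
  px <- function(um) as.integer(round(um / ps))
  m <- px(cfg$margin_um); e <- px(cfg$epiphysis_um)
  g <- px(cfg$growth_plate_um); d1 <- px(cfg$primary_um)
  d2 <- px(cfg$secondary_um); tl <- px(cfg$tail_um)
  pp <- max(2L, px(cfg$plate_um))
  W <- px(cfg$width_um); cx <- px(cfg$cortex_um)
  H <- 2L * m + e + g + d1 + d2 + tl
  trab_cols <- (cx + 1L):(W - cx)
  ntc <- length(trab_cols)
  dash_px <- cfg$dash_um / ps

  epi_rows <- (m + 1L):(m + e)
  gp_rows <- (m + e + 1L):(m + e + g)
  front <- m + e + g + 1L
  pri_rows <- front:(front + d1 - 1L)
  sec_rows <- (front + d1):(front + d1 + d2 - 1L)
  cortex_rows <- (m + 1L):(H - m)

  S <- matrix(FALSE, H, W)
  S[cortex_rows, c(1:cx, (W - cx + 1L):W)] <- TRUE

  # trabecular band fillers; seam plates border the growth plate and their
  # area is budgeted into the band targets so achieved BV/TV hits them
  rod_band <- function(rows_all, plate_at, tr) {
    plate_rows <- integer(0)
    rod_rows <- rows_all
    if (!is.na(plate_at)) {
      plate_rows <- if (plate_at == "bottom")
        rows_all[(length(rows_all) - pp + 1L):length(rows_all)]
      else rows_all[1:pp]
      rod_rows <- setdiff(rows_all, plate_rows)
    }
    target_area <- tr$bvtv / 100 * length(rows_all) * ntc
    rod_bvtv <- 100 * max(target_area - length(plate_rows) * ntc, 0) /
      (length(rod_rows) * ntc)
    rods <- dashed_rods(length(rod_rows), ntc, tr$tbth / ps, rod_bvtv,
                        cfg$rod_fill, dash_px)
    list(plate_rows = plate_rows, rod_rows = rod_rows, rods = rods)
  }
  epi <- rod_band(epi_rows, "bottom", cfg$trabecular$epiphysis)
  pri <- rod_band(pri_rows, "top", cfg$trabecular$primary)
  sec <- rod_band(sec_rows, NA, cfg$trabecular$secondary)
  S[epi$plate_rows, trab_cols] <- TRUE
  S[epi$rod_rows, trab_cols] <- S[epi$rod_rows, trab_cols] | epi$rods
  S[pri$plate_rows, trab_cols] <- TRUE
  S[pri$rod_rows, trab_cols] <- S[pri$rod_rows, trab_cols] | pri$rods
  S[sec_rows, trab_cols] <- S[sec_rows, trab_cols] | sec$rods

  lac <- stamp_lacunae(S, cortex_rows, 1:cx, cfg)
  S <- lac$S
  lac2 <- stamp_lacunae(S, cortex_rows, (W - cx + 1L):W, cfg)
  S <- lac2$S
  lacunae <- rbind(lac$truth, lac2$truth)

  # zone labels: 1 cortex, 2 epiphysis, 3 growth plate, 4 primary, 5 secondary
  Z <- matrix(0L, H, W)
  Z[epi_rows, trab_cols] <- 2L
  Z[gp_rows, trab_cols] <- 3L
  Z[pri_rows, trab_cols] <- 4L
  Z[sec_rows, trab_cols] <- 5L
  Z[cortex_rows, c(1:cx, (W - cx + 1L):W)] <- 1L

  ca <- matrix(stats::rnorm(H * W, cfg$ca$background["mean"],
                            cfg$ca$background["sd"]), H, W)
  zone_ca <- function(sel, p) {
    n <- sum(sel)
    if (n) ca[sel] <<- stats::rnorm(n, p["mean"], p["sd"])
  }
  zone_ca(S & Z == 1L, cfg$ca$cortex)
  zone_ca(S & Z == 2L, cfg$ca$epiphysis)
  zone_ca(S & (Z == 4L | Z == 5L), cfg$ca$metaphysis)
  ca[ca < 0] <- 0

  model <- fit_calibration(cfg$standards[["carbon"]],
                           cfg$standards[["aluminum"]], cfg$calibration)
  gray <- gray_from_ca(model, ca)
  if (cfg$noise_sd_gl > 0)
    gray <- gray + stats::rnorm(H * W, 0, cfg$noise_sd_gl)
  gray <- pmin(pmax(round(gray), 0), 255)
  storage.mode(gray) <- "integer"

  band_bvtv <- function(rows) 100 * mean(S[rows, trab_cols])
  truth <- list(
    seed = seed,
    front_row = front,
    band_rows = c(gp_rows[1], gp_rows[length(gp_rows)]),
    gp_height_px = g,
    gp_thickness_um = stats::setNames(rep(g * ps, ntc), trab_cols),
    trab_cols = trab_cols,
    achieved_bvtv = c(epiphysis = band_bvtv(epi_rows),
                      primary = band_bvtv(pri_rows),
                      secondary = band_bvtv(sec_rows)),
    planted_tbth = c(epiphysis = cfg$trabecular$epiphysis$tbth,
                     primary = cfg$trabecular$primary$tbth,
                     secondary = cfg$trabecular$secondary$tbth),
    lacunae = lacunae,
    zone_ca = cfg$ca)
  if (full_truth) {
    truth$zone <- Z
    truth$structure_mask <- S
  }
  structure(list(raw = gray, truth = truth,
                 meta = list(standards = cfg$standards, pixel_size = ps,
                             calibration = cfg$calibration)),
            class = "synthetic_bone_image")
}

#' @export
print.synthetic_bone_image <- function(x, ...) {
  cat(sprintf("synthetic qBEI image: %d x %d px at %.2f um/px, %d lacunae planted\n",
              nrow(x$raw), ncol(x$raw), x$meta$pixel_size,
              if (is.null(x$truth$lacunae)) 0L else nrow(x$truth$lacunae)))
  invisible(x)
}

scale_config <- function(cfg, jit, eff) {
  s <- function(name) (jit[[name]] %||% 1) * (eff[[name]] %||% 1)
  cfg$growth_plate_um <- cfg$growth_plate_um * s("growth_plate")
  cfg$trabecular$primary$bvtv <- cfg$trabecular$primary$bvtv * s("bvtv_primary")
  cfg$trabecular$secondary$bvtv <-
    cfg$trabecular$secondary$bvtv * s("bvtv_secondary")
  cfg$trabecular$epiphysis$bvtv <-
    cfg$trabecular$epiphysis$bvtv * s("bvtv_epiphysis")
  cfg$trabecular$primary$tbth <- cfg$trabecular$primary$tbth * s("tbth_primary")
  cfg$trabecular$secondary$tbth <-
    cfg$trabecular$secondary$tbth * s("tbth_secondary")
  cfg$trabecular$epiphysis$tbth <-
    cfg$trabecular$epiphysis$tbth * s("tbth_epiphysis")
  cfg$ca$cortex["mean"] <- cfg$ca$cortex["mean"] * s("ca_cortex")
  cfg$ca$epiphysis["mean"] <- cfg$ca$epiphysis["mean"] * s("ca_epiphysis")
  cfg$ca$metaphysis["mean"] <- cfg$ca$metaphysis["mean"] * s("ca_metaphysis")
  if (cfg$enforce_zone_order) {
    # jitter may break the ordering by chance; the planted gradient stays
    mns <- sort(c(cortex = cfg$ca$cortex[["mean"]],
                  epiphysis = cfg$ca$epiphysis[["mean"]],
                  metaphysis = cfg$ca$metaphysis[["mean"]]),
                decreasing = TRUE)
    cfg$ca$cortex["mean"] <- mns[1]
    cfg$ca$epiphysis["mean"] <- mns[2]
    cfg$ca$metaphysis["mean"] <- mns[3]
  }
  cfg
}

#' Generate a synthetic cohort with planted genotype effects
#'
#' Draws per-animal parameters around the config means (multiplicative
#' between-animal variation, truncated normal with coefficient of variation
#' `config$between_animal_cv`); mutant animals additionally receive the
#' effect-profile scalings. Images are materialized lazily through
#' [cohort_image()] to keep memory flat, or written to disk when
#' `write_dir` is given. Simulated empty/total lacuna counts (histology
#' surrogate) are included per animal.
#'
#' @param config base (wild-type) [synthetic_config()].
#' @param n_wt,n_mut group sizes.
#' @param age_group cohort age label; selects the shipped effect profile
#'   when `config$effect` is `NULL`.
#' @param seed integer seed governing all cohort-level randomness.
#' @param write_dir optional directory: writes 8-bit TIFFs, a manifest CSV
#'   and per-image ground-truth JSON.
#' @return object of class `synthetic_cohort`: `manifest` (data.frame),
#'   `samples` (per-animal configs and seeds), `counts` (lacuna counts),
#'   `profile`.
#' @export
generate_cohort <- function(config = synthetic_config(), n_wt, n_mut,
                            age_group = "8W", seed = 1, write_dir = NULL) {
  stopifnot(n_wt >= 1, n_mut >= 1)
  eff <- config$effect %||% effect_profile(age_group)
  cv <- config$between_animal_cv
  n <- n_wt + n_mut
  with_seed(seed, {
    seeds <- sample.int(2147483646L, n)
    genotype <- c(rep("WT", n_wt), rep("MUT", n_mut))
    sex <- c(rep_len(c("M", "F"), n_wt), rep_len(c("M", "F"), n_mut))
    jit_names <- c("growth_plate", "bvtv_primary", "bvtv_secondary",
                   "bvtv_epiphysis", "tbth_primary", "tbth_secondary",
                   "tbth_epiphysis", "ca_cortex", "ca_epiphysis",
                   "ca_metaphysis")
    counts_mean <- if (age_group == "15W") 2300 else 1400
    base_empty <- 0.10
    samples <- vector("list", n)
    counts <- data.frame(sample_id = character(n), n_empty = integer(n),
                         n_total = integer(n))
    for (i in seq_len(n)) {
      jit <- as.list(pmin(pmax(stats::rnorm(length(jit_names), 1, cv), 0.7),
                          1.3))
      names(jit) <- jit_names
      eff_i <- if (genotype[i] == "MUT") eff else list()
      cfg_i <- scale_config(config, jit, eff_i)
      sid <- sprintf("%s_%s_%02d", age_group, genotype[i], i)
      samples[[i]] <- list(sample_id = sid, config = cfg_i,
                           seed = seeds[i], genotype = genotype[i],
                           sex = sex[i], age_group = age_group,
                           jitter = jit)
      p_empty <- base_empty * (eff_i[["empty_fraction"]] %||% 1) *
        pmin(pmax(stats::rnorm(1, 1, cv), 0.7), 1.3)
      n_total <- max(50L, as.integer(round(stats::rnorm(1, counts_mean,
                                                        0.1 * counts_mean))))
      counts$sample_id[i] <- sid
      counts$n_empty[i] <- stats::rbinom(1, n_total, min(p_empty, 1))
      counts$n_total[i] <- n_total
    }
  })
  manifest <- data.frame(
    sample_id = vapply(samples, `[[`, "", "sample_id"),
    genotype = genotype, sex = sex, age_group = age_group,
    carbon_gl = config$standards[["carbon"]],
    aluminum_gl = config$standards[["aluminum"]],
    pixel_size = config$pixel_size,
    seed = seeds, path = NA_character_)
  cohort <- structure(list(manifest = manifest, samples = samples,
                           counts = counts, profile = eff,
                           base_config = config, seed = seed),
                      class = "synthetic_cohort")
  if (!is.null(write_dir)) cohort <- write_cohort(cohort, write_dir)
  cohort
}

#' Materialize one cohort image
#' @param cohort a `synthetic_cohort`.
#' @param i sample index or sample id.
#' @param full_truth see [generate_bone_image()].
#' @return a `synthetic_bone_image`.
#' @export
cohort_image <- function(cohort, i, full_truth = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.character(i))
    i <- match(i, cohort$manifest$sample_id)
  s <- cohort$samples[[i]]
  generate_bone_image(s$config, s$seed, full_truth = full_truth)
}

write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$samples)) {
    s <- cohort$samples[[i]]
    img <- cohort_image(cohort, i, full_truth = FALSE)
    path <- file.path(dir, paste0(s$sample_id, ".tif"))
    write_qbei_image(img$raw, path)
    jsonlite::write_json(
      img$truth[c("front_row", "band_rows", "gp_height_px", "achieved_bvtv",
                  "planted_tbth")],
      file.path(dir, paste0(s$sample_id, "_truth.json")), auto_unbox = TRUE,
      digits = NA)
    cohort$manifest$path[i] <- path
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$counts, file.path(dir, "lacuna_counts.csv"),
                   row.names = FALSE)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort (%s): %d WT / %d MUT, seed %d\n",
              x$manifest$age_group[1],
              sum(x$manifest$genotype == "WT"),
              sum(x$manifest$genotype == "MUT"), x$seed))
  invisible(x)
}
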