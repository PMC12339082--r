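#' Pipeline run configuration
#'
#' Collects the fixed constants of the quantification chain: the canonical
#' calibration, the 5.2 wt\%Ca mineralized/unmineralized boundary, the
#' 0.17 wt\%Ca histogram resolution, the 5-200 um^2 lacuna gate and the
#' 500/1000 um spongiosa band depths.
#'
#' @param pixel_size default micrometers per pixel (overridden by per-image
#'   metadata).
#' @param calibration canonical calibration constants.
#' @param mineral_threshold mineralized boundary, wt\%Ca.
#' @param bin_width BMDD bin width, wt\%Ca.
#' @param ols_gate lacuna section-area gate, um^2.
#' @param primary_um,secondary_um spongiosa band depths, um.
#' @param opening 3x3 opening passes before band/front search.
#' @param cortex_frac,band_frac,min_band_px band-search parameters, see
#'   [detect_mineralization_front()].
#' @param alpha significance level for the normality gate and tests.
#' @param tukey_family `"site"` or `"cells"`, see [two_way_anova_tukey()].
#' @param seed seed for any stochastic steps.
#' @return object of class `run_config` carrying a `hash` of all settings.
#' @export
run_config <- function(pixel_size = 0.88,
                       calibration = qbei_constants(),
                       mineral_threshold = 5.2,
                       bin_width = 0.17,
                       ols_gate = c(5, 200),
                       primary_um = 500,
                       secondary_um = 1000,
                       opening = 1,
                       cortex_frac = 0.85,
                       band_frac = 0.05,
                       min_band_px = 8,
                       alpha = 0.05,
                       tukey_family = "site",
                       seed = 1) {
  stopifnot(mineral_threshold > 0, bin_width > 0, all(ols_gate > 0),
            primary_um > 0, secondary_um > 0)
  cfg <- structure(as.list(environment()), class = "run_config")
  cfg$hash <- config_hash(cfg)
  cfg
}

#' Hash of a configuration
#'
#' MD5 over the canonical YAML serialization; recorded in every output so
#' results are traceable to the exact parameter set.
#'
#' @param config any list-like configuration.
#' @return hex string.
#' @export
config_hash <- function(config) {
  config$hash <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

resolve_image <- function(image, metadata) {
  if (inherits(image, "synthetic_bone_image")) {
    meta <- list(sample_id = metadata$sample_id %||% "synthetic",
                 carbon_gl = image$meta$standards[["carbon"]],
                 aluminum_gl = image$meta$standards[["aluminum"]],
                 pixel_size = image$meta$pixel_size)
    meta <- utils::modifyList(meta, metadata %||% list())
    return(list(raw = image$raw, meta = meta))
  }
  raw <- if (is.character(image)) read_qbei_image(image) else image
  if (!is.matrix(raw))
    oq_stop("image must be a path, matrix or synthetic_bone_image",
            "oq_io_error")
  list(raw = raw, meta = metadata %||% list())
}

#' Quantify one bone-section image
#'
#' Runs the full per-sample chain: standards calibration, calcium map,
#' mineral mask, automatic compartment segmentation (cortical columns, band
#' search for the growth plate), per-site BMDD, spongiosa histomorphometry,
#' growth-plate thickness and cortical OLS analysis. Stages that need a
#' growth-plate band report their failure in `notes` without aborting the
#' remaining stages.
#'
#' @param image file path (TIFF/PNG), gray-level matrix, or a
#'   `synthetic_bone_image`.
#' @param metadata list with at least `carbon_gl` and `aluminum_gl` (the
#'   measured standards), optionally `sample_id`, `pixel_size`, `genotype`,
#'   `sex`, `age_group`.
#' @param config a [run_config()].
#' @return object of class `sample_record`.
#' @export
run_sample <- function(image, metadata = list(), config = run_config()) {
  ri <- resolve_image(image, metadata)
  meta <- ri$meta
  if (is.null(meta$carbon_gl) || is.null(meta$aluminum_gl))
    oq_stop("metadata must provide the measured standards gray levels",
            "oq_metadata_error")
  ps <- meta$pixel_size %||% config$pixel_size
  notes <- character(0)

  model <- fit_calibration(meta$carbon_gl, meta$aluminum_gl,
                           config$calibration)
  camap <- apply_calibration(ri$raw, model, pixel_size = ps)
  mask <- make_mineral_mask(camap, threshold = config$mineral_threshold)
  dims <- dim(mask$mask)

  opened <- .binary_open3(as_int_mask(mask$mask),
                          as.integer(max(config$opening, 0))) > 0L
  cortex_cols <- which(colMeans(opened) >= config$cortex_frac)
  rois <- list()
  if (length(cortex_cols))
    rois$cortex <- roi_rect("cortex", seq_len(dims[1]), cortex_cols, dims)
  else notes <- c(notes, "no cortical columns found")

  front <- tryCatch(
    detect_mineralization_front(mask, opening = config$opening,
                                band_frac = config$band_frac,
                                cortex_frac = config$cortex_frac,
                                min_band_px = config$min_band_px),
    oq_front_not_found_error = function(e) {
      notes <<- c(notes, paste("front detection:", conditionMessage(e)))
      NULL
    })

  trab_cols <- setdiff(seq_len(dims[2]), cortex_cols)
  if (!is.null(front) && length(trab_cols)) {
    if (front$band_rows[1] > 1)
      rois$epiphysis <- roi_rect("epiphysis", 1:(front$band_rows[1] - 1),
                                 trab_cols, dims)
    if (front$band_rows[2] < dims[1])
      rois$metaphysis <- roi_rect("metaphysis",
                                  (front$band_rows[2] + 1):dims[1],
                                  trab_cols, dims)
    sp <- tryCatch(
      define_spongiosa_rois(front, pixel_size = ps,
                            primary_um = config$primary_um,
                            secondary_um = config$secondary_um),
      oq_empty_roi_error = function(e) {
        notes <<- c(notes, paste("spongiosa bands:", conditionMessage(e)))
        NULL
      })
    if (!is.null(sp)) {
      rois$primary_spongiosa <- sp$primary
      rois$secondary_spongiosa <- sp$secondary
    }
  }

  site_of <- c(cortex = "Ct", epiphysis = "Es", metaphysis = "Ms")
  curves <- list()
  bmdd <- NULL
  for (zone in names(site_of)) {
    if (is.null(rois[[zone]])) next
    cv <- tryCatch(
      compute_bmdd(camap, rois[[zone]], threshold = config$mineral_threshold,
                   bin_width = config$bin_width),
      oq_empty_region_error = function(e) NULL)
    if (is.null(cv)) {
      notes <- c(notes, sprintf("no mineralized pixels in %s", zone))
      next
    }
    curves[[site_of[[zone]]]] <- cv
    p <- bmdd_params(cv)
    bmdd <- rbind(bmdd, data.frame(site = site_of[[zone]],
                                   ca_mean = p$ca_mean, ca_peak = p$ca_peak,
                                   ca_width = p$ca_width))
  }

  histo <- NULL
  for (band in c("primary_spongiosa", "secondary_spongiosa")) {
    if (is.null(rois[[band]])) next
    hv <- bv_tv(mask, rois[[band]])
    th <- tryCatch(trabecular_thickness(mask, rois[[band]]),
                   oq_empty_phase_error = function(e) NA_real_)
    tn <- if (is.finite(th) && th > 0) trabecular_number(hv$bv_tv, th)
          else NA_real_
    histo <- rbind(histo, data.frame(
      region = sub("_spongiosa", "", band), bv_tv = hv$bv_tv, tb_th = th,
      tb_n = tn, bone_area = hv$bone_area, tissue_area = hv$tissue_area))
  }

  gp <- tryCatch(
    growth_plate_thickness(mask, opening = config$opening,
                           band_frac = config$band_frac,
                           cortex_frac = config$cortex_frac,
                           min_band_px = config$min_band_px),
    oq_front_not_found_error = function(e) {
      notes <<- c(notes, paste("growth plate:", conditionMessage(e)))
      NULL
    })

  ols <- NULL
  if (!is.null(rois$cortex)) {
    recs <- extract_ols(mask, min_area = config$ols_gate[1],
                        max_area = config$ols_gate[2], roi = rois$cortex)
    ols <- ols_summary(recs, mask, roi = rois$cortex)
    attr(ols, "records") <- recs
  }

  structure(list(sample_id = meta$sample_id %||% "sample",
                 metadata = meta, config_hash = config$hash,
                 curves = curves, bmdd = bmdd, histo = histo, gp = gp,
                 ols = ols, notes = notes, pixel_size = ps),
            class = "sample_record")
}

#' @export
print.sample_record <- function(x, ...) {
  cat(sprintf("sample_record '%s' (config %s)\n", x$sample_id,
              substr(x$config_hash %||% "", 1, 8)))
  if (!is.null(x$bmdd)) print(x$bmdd, digits = 4)
  if (!is.null(x$histo)) print(x$histo, digits = 4)
  if (!is.null(x$gp))
    cat(sprintf("growth plate: %.1f um (%d columns)\n",
                x$gp$mean_thickness, x$gp$n_valid_columns))
  if (!is.null(x$ols))
    cat(sprintf("OLS: n = %d, porosity %.2f%%\n", x$ols$n_lacunae,
                x$ols$ols_porosity))
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# long-format measurement rows for one sample record
measure_rows <- function(rec, extra = list()) {
  base <- data.frame(sample_id = rec$sample_id,
                     genotype = extra$genotype %||% NA_character_,
                     sex = extra$sex %||% NA_character_,
                     age_group = extra$age_group %||% NA_character_)
  out <- NULL
  add <- function(site, measure, value) {
    if (is.null(value) || !length(value) || !is.finite(value)) return()
    out <<- rbind(out, cbind(base, data.frame(site = site, measure = measure,
                                              value = value)))
  }
  if (!is.null(rec$bmdd))
    for (i in seq_len(nrow(rec$bmdd)))
      for (msr in c("ca_mean", "ca_peak", "ca_width"))
        add(rec$bmdd$site[i], msr, rec$bmdd[[msr]][i])
  if (!is.null(rec$histo))
    for (i in seq_len(nrow(rec$histo)))
      for (msr in c("bv_tv", "tb_th", "tb_n"))
        add(rec$histo$region[i], msr, rec$histo[[msr]][i])
  if (!is.null(rec$gp))
    add("growth_plate", "gp_thickness", rec$gp$mean_thickness)
  if (!is.null(rec$ols)) {
    add("Ct", "ols_porosity", rec$ols$ols_porosity)
    add("Ct", "ols_density", rec$ols$ols_density)
    add("Ct", "ols_median_area", rec$ols$median_area)
    add("Ct", "ols_median_perimeter", rec$ols$median_perimeter)
  }
  out
}

#' Quantify and compare a whole cohort
#'
#' Runs [run_sample()] over every cohort member (corrupt or unreadable
#' samples are skipped with a warning and listed in the report), builds the
#' reference BMDD from the wild-type metaphyseal curves of each age group,
#' derives CaLow/CaHigh for every sample against its age reference, and
#' compares genotype groups per measure with the normality-gated two-group
#' test.
#'
#' @param cohort a `synthetic_cohort`, or a manifest data.frame with
#'   columns `sample_id`, `path`, `genotype`, `sex`, `age_group`,
#'   `carbon_gl`, `aluminum_gl`, `pixel_size`.
#' @param config a [run_config()].
#' @param counts optional lacuna counts data.frame (`sample_id`, `n_empty`,
#'   `n_total`); defaults to the cohort's simulated counts if present.
#' @return object of class `cohort_report`: `measures` (long
#'   [cohort_table()]), `comparisons`, `reference` (per age), `records`,
#'   `excluded`, `config_hash`.
#' @export
run_cohort <- function(cohort, config = run_config(), counts = NULL) {
  if (inherits(cohort, "synthetic_cohort")) {
    manifest <- cohort$manifest
    counts <- counts %||% cohort$counts
    get_image <- function(i) cohort_image(cohort, i)
  } else {
    manifest <- cohort
    if (is.null(manifest$path))
      oq_stop("manifest must have a 'path' column", "oq_format_error")
    get_image <- function(i) manifest$path[i]
  }
  records <- list()
  excluded <- character(0)
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    rec <- tryCatch(
      run_sample(get_image(i),
                 metadata = list(sample_id = sid,
                                 carbon_gl = manifest$carbon_gl[i],
                                 aluminum_gl = manifest$aluminum_gl[i],
                                 pixel_size = manifest$pixel_size[i]),
                 config = config),
      error = function(e) {
        warning(sprintf("sample '%s' skipped: %s", sid, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(rec)) excluded <- c(excluded, sid) else records[[sid]] <- rec
  }
  if (!length(records))
    oq_stop("no sample could be processed", "oq_io_error")
  kept <- manifest[manifest$sample_id %in% names(records), ]

  rows <- NULL
  for (i in seq_len(nrow(kept))) {
    sid <- kept$sample_id[i]
    rows <- rbind(rows, measure_rows(records[[sid]],
                                     kept[i, c("genotype", "sex",
                                               "age_group")]))
  }

  # reference BMDD: wild-type metaphysis, per age group
  reference <- list()
  for (ag in unique(kept$age_group)) {
    wt_ids <- kept$sample_id[kept$genotype == "WT" & kept$age_group == ag]
    wt_curves <- lapply(records[wt_ids], function(r) r$curves$Ms)
    wt_curves <- Filter(Negate(is.null), wt_curves)
    if (!length(wt_curves)) {
      oq_stop(sprintf(
        "no wild-type metaphyseal BMDD available for age group '%s'", ag),
        "oq_reference_error")
    }
    reference[[ag]] <- reference_bmdd(wt_curves)
  }
  for (i in seq_len(nrow(kept))) {
    sid <- kept$sample_id[i]
    ref <- reference[[kept$age_group[i]]]
    for (site in names(records[[sid]]$curves)) {
      lh <- ca_low_high(records[[sid]]$curves[[site]], ref)
      rows <- rbind(rows, cbind(
        data.frame(sample_id = sid, genotype = kept$genotype[i],
                   sex = kept$sex[i], age_group = kept$age_group[i]),
        data.frame(site = site, measure = c("ca_low", "ca_high"),
                   value = unname(lh))))
    }
  }
  if (!is.null(counts)) {
    cm <- merge(kept[, c("sample_id", "genotype", "sex", "age_group")],
                counts, by = "sample_id")
    if (nrow(cm))
      rows <- rbind(rows, data.frame(
        sample_id = cm$sample_id, genotype = cm$genotype, sex = cm$sex,
        age_group = cm$age_group, site = "Ct", measure = "empty_fraction",
        value = empty_fraction(cm$n_empty, cm$n_total)))
  }
  rows <- cohort_table(rows)

  comparisons <- NULL
  keys <- unique(rows[, c("age_group", "site", "measure")])
  for (i in seq_len(nrow(keys))) {
    sel <- rows$age_group == keys$age_group[i] & rows$site == keys$site[i] &
      rows$measure == keys$measure[i]
    a <- rows$value[sel & rows$genotype == "WT"]
    b <- rows$value[sel & rows$genotype == "MUT"]
    if (length(a) < 3 || length(b) < 3) next
    gc <- tryCatch(compare_two_groups(a, b, alpha = config$alpha),
                   osteoquant_error = function(e) NULL)
    if (is.null(gc)) next
    comparisons <- rbind(comparisons, cbind(
      keys[i, , drop = FALSE],
      data.frame(test = gc$test_name, statistic = gc$statistic,
                 p_value = gc$p_value, mean_wt = gc$mean_a,
                 mean_mut = gc$mean_b,
                 percent_difference = gc$percent_difference,
                 n_wt = gc$n_a, n_mut = gc$n_b)))
  }
  rownames(comparisons) <- NULL
  structure(list(measures = rows, comparisons = comparisons,
                 reference = reference, records = records,
                 excluded = excluded, config_hash = config$hash),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort_report: %d samples (%d excluded), config %s\n",
              length(x$records), length(x$excluded),
              substr(x$config_hash %||% "", 1, 8)))
  if (!is.null(x$comparisons)) {
    sig <- x$comparisons[x$comparisons$p_value < 0.05, ]
    cat(sprintf("%d comparisons, %d with p < 0.05\n",
                nrow(x$comparisons), nrow(sig)))
    if (nrow(sig))
      print(sig[, c("age_group", "site", "measure", "test", "p_value",
                    "percent_difference")], digits = 3)
  }
  invisible(x)
}

#' Write a QC overlay image
#'
#' Renders the mineral mask in gray with ROI boundaries highlighted, as a
#' quick visual check of segmentation and band placement.
#'
#' @param mask a `mineral_mask`.
#' @param rois list of [roi_spec()] objects.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_qc_overlay <- function(mask, rois, path) {
  m <- mask$mask
  img <- array(0, c(nrow(m), ncol(m), 3))
  img[, , 1] <- img[, , 2] <- img[, , 3] <- 0.75 * m
  for (roi in rois) {
    edge <- dilate3(roi$mask) & !roi$mask
    img[, , 1][edge] <- 1
    img[, , 2][edge] <- 0.2
    img[, , 3][edge] <- 0.2
  }
  png::writePNG(img, path)
  invisible(path)
}
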