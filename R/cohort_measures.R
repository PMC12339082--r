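#' Measure selected stage outputs over a synthetic cohort
#'
#' Convenience driver for effect-recovery studies: materializes each cohort
#' image in turn, runs only the pipeline stages the requested measures
#' need (growth-plate scan; front detection plus band histomorphometry),
#' and returns one row per animal and measure. Memory stays flat because
#' images are discarded after measurement.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param measures subset of `gp_thickness`, `bv_tv.primary`,
#'   `bv_tv.secondary`, `tb_th.primary`, `tb_th.secondary`,
#'   `tb_n.primary`, `tb_n.secondary`.
#' @param config a [run_config()].
#' @return data.frame with `sample_id`, `genotype`, `measure`, `value`.
#' @export
measure_cohort <- function(cohort,
                           measures = "gp_thickness",
                           config = run_config()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  known <- c("gp_thickness", "bv_tv.primary", "bv_tv.secondary",
             "tb_th.primary", "tb_th.secondary", "tb_n.primary",
             "tb_n.secondary")
  bad <- setdiff(measures, known)
  if (length(bad))
    oq_stop(paste("unknown measures:", paste(bad, collapse = ", ")),
            "oq_domain_error")
  need_bands <- any(measures != "gp_thickness")
  out <- NULL
  for (i in seq_len(nrow(cohort$manifest))) {
    img <- cohort_image(cohort, i)
    model <- fit_calibration(img$meta$standards[["carbon"]],
                             img$meta$standards[["aluminum"]],
                             config$calibration)
    camap <- apply_calibration(img$raw, model,
                               pixel_size = img$meta$pixel_size)
    mask <- make_mineral_mask(camap, threshold = config$mineral_threshold)
    vals <- c()
    if ("gp_thickness" %in% measures)
      vals["gp_thickness"] <-
        growth_plate_thickness(mask, opening = config$opening,
                               band_frac = config$band_frac,
                               cortex_frac = config$cortex_frac,
                               min_band_px = config$min_band_px)$mean_thickness
    if (need_bands) {
      front <- detect_mineralization_front(mask, opening = config$opening,
                                           band_frac = config$band_frac,
                                           cortex_frac = config$cortex_frac,
                                           min_band_px = config$min_band_px)
      sp <- define_spongiosa_rois(front,
                                  primary_um = config$primary_um,
                                  secondary_um = config$secondary_um)
      for (band in c("primary", "secondary")) {
        sel <- grepl(paste0("\\.", band, "$"), measures)
        if (!any(sel)) next
        bvtv <- bv_tv(mask, sp[[band]])$bv_tv
        th <- NA_real_
        if (any(grepl("^tb_", measures[sel])))
          th <- trabecular_thickness(mask, sp[[band]])
        if (paste0("bv_tv.", band) %in% measures)
          vals[paste0("bv_tv.", band)] <- bvtv
        if (paste0("tb_th.", band) %in% measures)
          vals[paste0("tb_th.", band)] <- th
        if (paste0("tb_n.", band) %in% measures)
          vals[paste0("tb_n.", band)] <- trabecular_number(bvtv, th)
      }
    }
    out <- rbind(out, data.frame(
      sample_id = cohort$manifest$sample_id[i],
      genotype = cohort$manifest$genotype[i],
      measure = names(vals), value = unname(vals), row.names = NULL))
  }
  out
}

#' Percent group difference of a measured cohort
#'
#' @param measured data.frame from [measure_cohort()].
#' @param measure measure name to summarize.
#' @return percent difference of the mutant group mean against the
#'   wild-type group mean.
#' @export
cohort_percent_difference <- function(measured, measure) {
  v <- measured[measured$measure == measure, ]
  percent_difference(mean(v$value[v$genotype == "WT"]),
                     mean(v$value[v$genotype == "MUT"]))
}
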