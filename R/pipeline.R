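# Pipeline orchestration: simulate -> calibrate -> measure -> compare,
# with CSV report writers.

#' Pipeline configuration
#'
#' Collects the method constants: working resolution 17 px/mm, filter bank
#' 2..256 px in sqrt(2) steps, Gabor sigma 5 px, alpha 0.05. All stages
#' read these from the config rather than hard-coding them.
#'
#' @param pixels_per_mm working spatial resolution.
#' @param bank_min,bank_max,bank_factor filter-bank geometry.
#' @param gabor_sigma Gabor scale for edge disruption (px).
#' @param alpha significance level for all tests.
#' @param seed master seed for simulation.
#' @param cohort a [cohort_spec()], or a preset name (`"paper-mimic"`,
#'   `"null"`).
#' @param n_per_cell optional cell-size override for preset cohorts.
#' @param image_size scene side for preset cohorts.
#' @param out_dir optional report directory; reports are written when set.
#' @return an object of class `cq_config`.
#' @export
pipeline_config <- function(pixels_per_mm = 17, bank_min = 2, bank_max = 256,
                            bank_factor = sqrt(2), gabor_sigma = 5,
                            alpha = 0.05, seed = 1L, cohort = "paper-mimic",
                            n_per_cell = NULL, image_size = 160,
                            out_dir = NULL) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (gabor_sigma <= 0) stopf("gabor_sigma must be positive")
  structure(list(pixels_per_mm = pixels_per_mm, bank_min = bank_min,
                 bank_max = bank_max, bank_factor = bank_factor,
                 gabor_sigma = gabor_sigma, alpha = alpha,
                 seed = as.integer(seed), cohort = cohort,
                 n_per_cell = n_per_cell, image_size = image_size,
                 out_dir = out_dir),
            class = "cq_config")
}

resolve_cohort <- function(config) {
  ch <- config$cohort
  if (inherits(ch, "cq_cohort_spec")) return(ch)
  if (identical(ch, "paper-mimic"))
    return(paper_mimic_cohort(master_seed = config$seed,
                              n_per_cell = config$n_per_cell,
                              image_size = config$image_size))
  if (identical(ch, "null"))
    return(paper_mimic_cohort(master_seed = config$seed,
                              n_per_cell = config$n_per_cell,
                              image_size = config$image_size,
                              effects = "none"))
  stopf("unknown cohort preset '%s'", ch)
}

#' Measure one scene bundle
#'
#' Calibrates the raw image from its gray standards, resamples to the
#' working resolution if needed, and computes the granularity descriptors
#' of target and background, the GabRat edge disruption of the target, and
#' the per-region channel means.
#'
#' @param scene a scene bundle: list with `raw`, `masks` (`target`,
#'   `background`) and `standards`, as produced by [generate_scene()] or
#'   [load_scene()].
#' @param config a [pipeline_config()].
#' @return one-row data.frame of measurements.
#' @export
measure_scene <- function(scene, config = pipeline_config()) {
  measured <- measure_gray_patches(scene$raw, scene$standards)
  map <- fit_gray_calibration(measured, scene$standards$reflectances)
  stack <- apply_calibration(scene$raw, map)
  tmask <- scene$masks$target
  bmask <- scene$masks$background
  if (abs(stack$pixels_per_mm - config$pixels_per_mm) > 1e-9) {
    stack <- rescale_to_resolution(stack, config$pixels_per_mm)
    resize_mask <- function(m) {
      r <- EBImage::imageData(EBImage::resize(EBImage::Image(unclass(m) * 1),
                                              w = nrow(stack$R),
                                              h = ncol(stack$R)))
      region_mask(r > 0.5, mask_role(m))
    }
    tmask <- resize_mask(tmask)
    bmask <- resize_mask(bmask)
  }
  bank <- build_filter_bank(config$bank_min, config$bank_max,
                            config$bank_factor)
  pc <- pattern_channel(stack)
  dt <- pattern_descriptors(bandpass_energy(pc, tmask, bank))
  db <- pattern_descriptors(bandpass_energy(pc, bmask, bank))
  gr <- gabrat_mean(stack, tmask, sigma = config$gabor_sigma)
  cm <- region_channel_means(stack, tmask, bmask)
  names(db) <- paste0("bg_", names(db))
  cbind(dt, db, cm,
        data.frame(gabrat_R = gr$per_channel[["R"]],
                   gabrat_G = gr$per_channel[["G"]],
                   gabrat_B = gr$per_channel[["B"]],
                   mean_gabrat = gr$mean_gabrat,
                   n_edge = gr$n_edge, sigma = gr$sigma,
                   classification = classify_disruption(gr$mean_gabrat)))
}

#' Measure every scene of a cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @param config a [pipeline_config()].
#' @return data.frame with one row per individual (id, species, sex +
#'   [measure_scene()] columns).
#' @export
measure_cohort <- function(cohort, config = pipeline_config()) {
  rows <- lapply(seq_len(nrow(cohort$truth)), function(i) {
    tr <- cohort$truth[i, ]
    cbind(data.frame(id = tr$id, species = tr$species, sex = tr$sex),
          measure_scene(cohort$scenes[[tr$id]], config))
  })
  do.call(rbind, rows)
}

DESCRIPTOR_RESPONSES <- c("log10_e_max", "log10_filter_max", "log10_e_prop")

#' Group-comparison analysis of a measurement table
#'
#' Runs the full statistical battery: two-factor MANOVA (Wilks) and ANOVAs
#' with Tukey comparisons on the target pattern descriptors (log10 scale)
#' and on mean GabRat (raw scale), the same MANOVA/ANOVAs on the background
#' descriptors, paired t-tests of target vs background descriptors within
#' each group, and the background-matching major-axis table.
#'
#' @param meas a [measure_cohort()] data.frame.
#' @param alpha significance level.
#' @return list of class `cq_report` with `manova_target`,
#'   `manova_background`, `anova_target`, `anova_background`,
#'   `anova_gabrat`, `tukey`, `paired`, `matching`, `alpha`.
#' @export
analyze_measurements <- function(meas, alpha = 0.05) {
  meas$species <- factor(meas$species)
  meas$sex <- factor(meas$sex)
  cells <- interaction(meas$species, meas$sex, sep = ":")
  manova_target <- manova_wilks(meas, DESCRIPTOR_RESPONSES)
  bgr <- paste0("bg_", DESCRIPTOR_RESPONSES)
  manova_background <- manova_wilks(meas, bgr)
  stack_anova <- function(responses) {
    do.call(rbind, lapply(responses, function(r) {
      a <- two_way_anova(meas, r)
      cbind(data.frame(response = r), as.data.frame(a))
    }))
  }
  anova_target <- stack_anova(DESCRIPTOR_RESPONSES)
  anova_background <- stack_anova(bgr)
  anova_gabrat <- cbind(data.frame(response = "mean_gabrat"),
                        as.data.frame(two_way_anova(meas, "mean_gabrat")))
  tukey <- lapply(setNames(nm = c(DESCRIPTOR_RESPONSES, "mean_gabrat")),
                  function(r) tukey_hsd(meas[[r]], cells, alpha = alpha))
  paired <- do.call(rbind, lapply(levels(meas$species), function(sp) {
    do.call(rbind, lapply(levels(meas$sex), function(sx) {
      rows <- meas[meas$species == sp & meas$sex == sx, ]
      if (nrow(rows) < 2) return(NULL)
      do.call(rbind, lapply(DESCRIPTOR_RESPONSES, function(r) {
        tv <- rows[[r]]; bv <- rows[[paste0("bg_", r)]]
        # degenerate (constant-difference) pairs are reported, not fatal
        pt <- tryCatch(paired_t(tv, bv), error = function(e) NULL)
        data.frame(species = sp, sex = sx, response = r,
                   mean_target = mean(tv),
                   se_target = sd(tv) / sqrt(length(tv)),
                   mean_background = mean(bv),
                   se_background = sd(bv) / sqrt(length(bv)),
                   t = if (is.null(pt)) NA_real_ else pt$t,
                   df = length(tv) - 1,
                   p = if (is.null(pt)) NA_real_ else pt$p)
      }))
    }))
  }))
  matching <- matching_summary(meas, alpha = alpha)
  structure(list(manova_target = manova_target,
                 manova_background = manova_background,
                 anova_target = anova_target,
                 anova_background = anova_background,
                 anova_gabrat = anova_gabrat, tukey = tukey,
                 paired = paired, matching = matching, alpha = alpha),
            class = "cq_report")
}

tukey_table <- function(tukey) {
  do.call(rbind, lapply(names(tukey), function(r) {
    tk <- tukey[[r]]
    cbind(data.frame(response = r), tk$comparisons,
          letters = paste(names(tk$letters), tk$letters, sep = "=",
                          collapse = "; "))
  }))
}

#' Write a report bundle to CSV
#'
#' @param meas measurement table.
#' @param report an [analyze_measurements()] result.
#' @param config the [pipeline_config()] used.
#' @param out_dir output directory.
#' @return invisibly, the vector of file paths written.
#' @export
write_report_bundle <- function(meas, report, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    measurements = "measurements.csv",
    manova = "manova.csv",
    anova_pattern_target = "anova_pattern_target.csv",
    anova_pattern_background = "anova_pattern_background.csv",
    paired_target_background = "paired_target_background.csv",
    ma_regression = "ma_regression.csv",
    anova_gabrat = "anova_gabrat.csv",
    tukey = "tukey.csv")
  paths <- vapply(paths, function(p) file.path(out_dir, p), character(1))
  write.csv(meas, paths["measurements"], row.names = FALSE)
  manova_all <- rbind(cbind(data.frame(table = "target"),
                            as.data.frame(report$manova_target)),
                      cbind(data.frame(table = "background"),
                            as.data.frame(report$manova_background)))
  write.csv(manova_all, paths["manova"], row.names = FALSE)
  write.csv(report$anova_target, paths["anova_pattern_target"],
            row.names = FALSE)
  write.csv(report$anova_background, paths["anova_pattern_background"],
            row.names = FALSE)
  write.csv(report$paired, paths["paired_target_background"],
            row.names = FALSE)
  write.csv(report$matching, paths["ma_regression"], row.names = FALSE)
  write.csv(report$anova_gabrat, paths["anova_gabrat"], row.names = FALSE)
  write.csv(tukey_table(report$tukey), paths["tukey"], row.names = FALSE)
  meta <- list(
    package = "camoquant",
    version = as.character(utils::packageVersion("camoquant")),
    seed = config$seed,
    config = config[c("pixels_per_mm", "bank_min", "bank_max",
                      "bank_factor", "gabor_sigma", "alpha",
                      "n_per_cell", "image_size")],
    decisions = c(
      "descriptor group statistics on log10 scale; GabRat on raw scale",
      "Type III sums of squares with sum-to-zero contrasts",
      "Tukey-Kramer standard errors for unbalanced cells",
      "filter bank partitions the whole non-DC spectrum (open outer bands)",
      "Filter_max ties resolve to the smallest size",
      "zero-energy edge pixels skipped in GabRat",
      "slope tests reported where the regression correlation is significant"))
  meta_path <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, run_metadata = meta_path))
}

#' Run the full pipeline
#'
#' Simulate (or accept) a cohort, calibrate and measure every scene, run
#' the group statistics, and optionally write the report CSVs. Identical
#' config and seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return list of class `cq_bundle` with `truth`, `measurements`,
#'   `report`, `config` (and `paths` when reports were written).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "cq_config"))
  cohort_sp <- resolve_cohort(config)
  cohort <- generate_cohort(cohort_sp)
  meas <- measure_cohort(cohort, config)
  report <- analyze_measurements(meas, alpha = config$alpha)
  bundle <- structure(list(truth = cohort$truth, measurements = meas,
                           report = report, config = config),
                      class = "cq_bundle")
  if (!is.null(config$out_dir))
    bundle$paths <- write_report_bundle(meas, report, config,
                                        config$out_dir)
  bundle
}
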