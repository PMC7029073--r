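# Synthetic camouflage scenes with known ground truth.
#
# A scene is a textured background with a dominant spatial scale, an
# elliptical banded target whose marking period, contrast, diversity and
# mean-colour offset are controlled, optional boundary-crossing
# ("disruptive") elements, and gray-standard patches rendered through a
# known linear sensor response plus Gaussian noise. Every generator
# parameter maps to a measurable pipeline quantity: band period ->
# Filter_max, band contrast -> e_max, band diversity -> e_prop, disruption
# -> GabRat, mean offset / tracking slope -> major-axis slope.

#' Synthetic scene specification
#'
#' @param image_size side of the square image in px.
#' @param pixels_per_mm spatial resolution (the standard working scale is
#'   17 px/mm).
#' @param bg_period dominant background texture period in px.
#' @param bg_contrast background texture contrast (SD of reflectance,
#'   16-bit units).
#' @param bg_mean background mean reflectance per channel (16-bit units).
#' @param target_axes full ellipse axes of the target in px (rows, cols).
#' @param band_period dominant marking period of the target bands in px.
#' @param band_contrast marking contrast (SD of the dominant band,
#'   16-bit units).
#' @param band_count_diversity number of distinct band frequencies (>= 1);
#'   more frequencies lower e_prop.
#' @param band_angle band orientation in radians, or `NULL` to draw
#'   uniformly from the seed.
#' @param disruption fraction in `[0, 1]` of boundary-crossing texture:
#'   radial stripes phase-continuous across the outline, oriented across
#'   the boundary.
#' @param disruption_period spatial wavelength of the boundary-crossing
#'   stripes along the outline, in px. Effective disruptive markings are
#'   sized to the viewer's acuity; the default (10 px) matches the scale
#'   probed by a sigma = 5 Gabor at 17 px/mm.
#' @param matching_offset per-channel additive offset of the target mean
#'   reflectance from the background mean.
#' @param gray_reflectances known reflectances of the corner gray patches.
#' @param patch_size side of each gray patch in px.
#' @param sensor_gain,sensor_offset per-channel linear sensor response:
#'   `raw = (reflectance - sensor_offset) / sensor_gain`, so calibration
#'   should recover `reflectance = sensor_gain * raw + sensor_offset`.
#' @param noise_sd additive Gaussian sensor noise (raw units, applied
#'   before calibration).
#' @param seed integer seed; the scene is deterministic given the spec.
#' @return an object of class `cq_scene_spec` (a validated list).
#' @export
scene_spec <- function(image_size = 160, pixels_per_mm = 17,
                       bg_period = 24, bg_contrast = 1200,
                       bg_mean = c(R = 24000, G = 26000, B = 20000),
                       target_axes = c(56, 38),
                       band_period = 8, band_contrast = 2500,
                       band_count_diversity = 1L, band_angle = NULL,
                       disruption = 0, disruption_period = 10,
                       matching_offset = c(0, 0, 0),
                       gray_reflectances = c(0.1, 0.3, 0.6, 0.9),
                       patch_size = 12, sensor_gain = c(1.15, 1.2, 1.1),
                       sensor_offset = c(-1500, -2000, -1000),
                       noise_sd = 60, seed = 1L) {
  spec <- list(image_size = as.integer(image_size),
               pixels_per_mm = pixels_per_mm,
               bg_period = bg_period, bg_contrast = bg_contrast,
               bg_mean = setNames(rep_len(as.numeric(bg_mean), 3), CHANNELS),
               target_axes = rep_len(target_axes, 2),
               band_period = band_period, band_contrast = band_contrast,
               band_count_diversity = as.integer(band_count_diversity),
               band_angle = band_angle, disruption = disruption,
               disruption_period = disruption_period,
               matching_offset = setNames(
                 rep_len(as.numeric(matching_offset), 3), CHANNELS),
               gray_reflectances = gray_reflectances,
               patch_size = as.integer(patch_size),
               sensor_gain = setNames(rep_len(sensor_gain, 3), CHANNELS),
               sensor_offset = setNames(rep_len(sensor_offset, 3), CHANNELS),
               noise_sd = noise_sd, seed = as.integer(seed))
  with(spec, {
    if (image_size < 32) stopf("image_size must be at least 32 px")
    for (v in c("pixels_per_mm", "bg_period", "bg_contrast", "band_period",
                "band_contrast", "patch_size", "disruption_period"))
      if (spec[[v]] <= 0) stopf("%s must be positive", v)
    if (band_count_diversity < 1) stopf("band_count_diversity must be >= 1")
    if (disruption < 0 || disruption > 1)
      stopf("disruption must lie in [0, 1]")
    if (noise_sd < 0) stopf("noise_sd must be non-negative")
    if (length(gray_reflectances) < 2 ||
        any(gray_reflectances < 0 | gray_reflectances > 1))
      stopf("need >= 2 gray reflectances in [0, 1]")
    if (any(sensor_gain <= 0)) stopf("sensor_gain must be positive")
  })
  structure(spec, class = "cq_scene_spec")
}

# Band-limited Gaussian noise field with dominant period `period`,
# unit SD, on an n x n grid.
bandlimited_noise <- function(n, period) {
  w <- matrix(rnorm(n * n), n, n)
  f <- fft(w)
  P <- period_grid(n, n)
  sel <- P >= period / sqrt(2) & P < period * sqrt(2)
  sel[1, 1] <- FALSE
  if (!any(sel)) stopf("background period %g not representable at %d px",
                       period, n)
  f[!sel] <- 0i
  x <- Re(fft(f, inverse = TRUE)) / length(f)
  x / sd(x)
}

#' Render a synthetic scene
#'
#' Deterministic given the spec (including its seed). The background
#' region mask is an elliptical annulus adjacent to the target whose area
#' matches the target area within 10%.
#'
#' @param spec a [scene_spec()].
#' @return list of class `cq_scene` with elements `raw` ([raw_image()]),
#'   `masks` (list `target`, `background` of [region_mask()]),
#'   `standards` ([gray_standard_set()]), `truth` (ground-truth list),
#'   `patch_annotations`, `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "cq_scene_spec"))
  with_seed(spec$seed, {
    n <- spec$image_size
    ctr <- (n + 1) / 2
    sa <- spec$target_axes[1] / 2 # semi-axis along rows
    sb <- spec$target_axes[2] / 2 # semi-axis along cols
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    rho <- sqrt(((rows - ctr) / sa)^2 + ((cols - ctr) / sb)^2)
    target <- rho <= 1
    rho_out <- sqrt(1 + 1.05^2) # annulus area == target area (continuous)
    annulus <- rho > 1.05 & rho <= rho_out
    if (rho_out * max(sa, sb) > n / 2 - spec$patch_size - 2)
      stopf("target (with its background annulus) larger than image")

    # gray patches in the four corners
    m <- 3L
    ps <- spec$patch_size
    anchors <- list(c(m + 1L, m + 1L), c(m + 1L, n - m - ps + 1L),
                    c(n - m - ps + 1L, m + 1L),
                    c(n - m - ps + 1L, n - m - ps + 1L))
    refls <- spec$gray_reflectances
    if (length(refls) > 4) stopf("at most 4 corner gray patches supported")
    patch_masks <- list()
    patch_ann <- list()
    patch_all <- matrix(FALSE, n, n)
    for (i in seq_along(refls)) {
      a <- anchors[[i]]
      pm <- matrix(FALSE, n, n)
      pm[a[1]:(a[1] + ps - 1L), a[2]:(a[2] + ps - 1L)] <- TRUE
      if (any(pm & target)) stopf("gray patch overlaps the target")
      patch_masks[[i]] <- pm
      patch_all <- patch_all | pm
      patch_ann[[i]] <- list(rect = c(a[1], a[2], ps),
                             reflectance = refls[i])
    }
    annulus <- annulus & !patch_all

    # background texture, demeaned over the annulus so the rendered
    # background mean equals bg_mean by construction
    bg_tex <- bandlimited_noise(n, spec$bg_period) * spec$bg_contrast
    bg_tex <- bg_tex - mean(bg_tex[annulus])

    # target banding: sinusoids at band_period and harmonically spaced
    # companions; the dominant band gets a larger amplitude so Filter_max
    # recovery is well defined
    ang <- if (is.null(spec$band_angle)) runif(1, 0, pi) else spec$band_angle
    u <- cos(ang) * (rows - ctr) + sin(ang) * (cols - ctr)
    k <- spec$band_count_diversity
    pattern <- 0
    for (j in seq_len(k)) {
      pj <- spec$band_period * 2^(j - 1)
      amp <- spec$band_contrast * sqrt(2) * if (j == 1) 1.25 else 0.85
      pattern <- pattern + amp * sin(2 * pi * u / pj + runif(1, 0, 2 * pi))
    }
    # background-matching markings fade before the body outline (the
    # classic contrast with disruptive elements, which cross it); a cosine
    # ramp over ~6 px keeps band terminations away from the edge detector
    w_in <- 6 / sqrt(sa * sb)
    ramp <- 0.5 - 0.5 * cos(pi * pmin(1, pmax(0, (1 - rho) / w_in)))
    pattern <- pattern * ramp
    pattern <- pattern - mean(pattern[target])

    # disruptive elements: radial stripes phase-continuous across the
    # outline, confined to a tapered ring straddling the boundary
    disr <- 0
    if (spec$disruption > 0) {
      phi <- atan2((cols - ctr) / sb, (rows - ctr) / sa)
      per <- pi * (sa + sb)
      n_spokes <- max(4L, round(per / spec$disruption_period))
      w <- 5 / sqrt(sa * sb)
      taper <- pmax(0, 0.5 * (1 + cos(pi * (rho - 1) / w)) * (abs(rho - 1) < w))
      amp_d <- spec$disruption * 1.5 * spec$band_contrast * sqrt(2)
      disr <- amp_d * cos(n_spokes * phi + runif(1, 0, 2 * pi)) * taper
    }

    refl <- list()
    for (ch in CHANNELS) {
      base <- spec$bg_mean[[ch]] + bg_tex
      base[target] <- spec$bg_mean[[ch]] + spec$matching_offset[[ch]] +
        pattern[target]
      base <- base + disr
      for (i in seq_along(refls))
        base[patch_masks[[i]]] <- refls[i] * REFL_MAX
      refl[[ch]] <- pmin(pmax(base, 0), REFL_MAX)
    }

    raw_ch <- lapply(CHANNELS, function(ch) {
      v <- (refl[[ch]] - spec$sensor_offset[[ch]]) / spec$sensor_gain[[ch]]
      if (spec$noise_sd > 0) v <- v + rnorm(length(v), 0, spec$noise_sd)
      matrix(pmin(pmax(v, 0), REFL_MAX), n, n)
    })
    raw <- raw_image(raw_ch[[1]], raw_ch[[2]], raw_ch[[3]],
                     bit_depth = 16, pixels_per_mm = spec$pixels_per_mm)

    truth <- list(
      band_period = spec$band_period, band_contrast = spec$band_contrast,
      band_count = k, disruption = spec$disruption,
      bg_period = spec$bg_period,
      target_mean = spec$bg_mean + spec$matching_offset,
      bg_mean = spec$bg_mean,
      calibration = list(gain = spec$sensor_gain,
                         offset = spec$sensor_offset))
    structure(list(
      raw = raw,
      masks = list(target = region_mask(target, "target"),
                   background = region_mask(annulus, "background")),
      standards = gray_standard_set(patch_masks, refls),
      truth = truth, patch_annotations = patch_ann, spec = spec),
      class = "cq_scene")
  })
}

#' Cohort specification for species-by-sex scene sets
#'
#' @param cells list of per-cell lists; each cell needs `species`, `sex`,
#'   `n` (>= 3) and optionally any of the per-cell parameters below.
#' @param master_seed integer; per-scene seeds are derived from it and the
#'   scene index only, so cohorts are reproducible and order-independent.
#' @param image_size,pixels_per_mm,bg_period,bg_contrast passed to every
#'   scene.
#' @param defaults named list of per-cell parameter defaults; per-cell
#'   values override. Recognised entries: `band_period`,
#'   `band_period_jitter` (SD of the per-individual log marking period,
#'   emulating natural variation in marking size), `band_contrast_mu`,
#'   `band_contrast_sd`, `band_count`, `disruption`, `matching_slope`
#'   (per-channel tracking of the background mean; 1 = perfect matching),
#'   `matching_offset` (per-channel), `matching_resid_sd` (SD of a shared
#'   luminance deviation of the target from its matched mean),
#'   `bg_mean_mu` (per-channel), `bg_lightness_cv` (CV of the shared
#'   background lightness factor across individuals), `bg_chroma_sd`
#'   (per-channel independent background variation), `axes_mu`,
#'   `axes_jitter`, `noise_sd`.
#' @return an object of class `cq_cohort_spec`.
#' @export
cohort_spec <- function(cells, master_seed = 1L, image_size = 160,
                        pixels_per_mm = 17, bg_period = 24,
                        bg_contrast = 1200, defaults = list()) {
  base <- list(band_period = 8, band_period_jitter = 0.2,
               band_contrast_mu = 2500,
               band_contrast_sd = 300, band_count = 1L, disruption = 0,
               matching_slope = c(1, 1, 1), matching_offset = c(0, 0, 0),
               matching_resid_sd = 400,
               bg_mean_mu = c(R = 24000, G = 26000, B = 20000),
               bg_lightness_cv = 0.15, bg_chroma_sd = 500,
               axes_mu = c(56, 38), axes_jitter = 0.08, noise_sd = 60)
  base[names(defaults)] <- defaults
  cells <- lapply(cells, function(cell) {
    if (is.null(cell$species) || is.null(cell$sex) || is.null(cell$n))
      stopf("each cell needs species, sex and n")
    if (cell$n < 3) stopf("each cell needs n >= 3")
    pars <- base
    override <- intersect(names(cell), names(base))
    pars[override] <- cell[override]
    c(cell[c("species", "sex", "n")], pars)
  })
  structure(list(cells = cells, master_seed = as.integer(master_seed),
                 image_size = as.integer(image_size),
                 pixels_per_mm = pixels_per_mm, bg_period = bg_period,
                 bg_contrast = bg_contrast),
            class = "cq_cohort_spec")
}

#' Generate a cohort of scenes with its ground-truth table
#'
#' @param spec a [cohort_spec()].
#' @param write_dir optional directory; if given, scenes are written via
#'   [write_scene()] and the truth table as `truth.csv`.
#' @return list with `scenes` (list of `cq_scene`), `truth` (data.frame,
#'   one row per individual) and `spec`.
#' @export
generate_cohort <- function(spec, write_dir = NULL) {
  stopifnot(inherits(spec, "cq_cohort_spec"))
  scenes <- list()
  truth <- list()
  for (ci in seq_along(spec$cells)) {
    cell <- spec$cells[[ci]]
    # one well-seeded stream per cell: parameter draws for all the cell's
    # individuals come sequentially from it (guaranteeing independent
    # draws), and each scene gets an unrelated rendering seed from the
    # same stream. Depends only on (master seed, cell index), so cohorts
    # are reproducible and cells are order-independent.
    cell_draws <- with_seed(derive_seed(spec$master_seed, ci), {
      lapply(seq_len(cell$n), function(i) {
        L <- rnorm(1, 1, cell$bg_lightness_cv)
        bg_mean <- pmax(cell$bg_mean_mu * L +
                          rnorm(3, 0, cell$bg_chroma_sd), 2000)
        eps <- rnorm(1, 0, cell$matching_resid_sd)
        slope <- rep_len(cell$matching_slope, 3)
        off <- (slope - 1) * (bg_mean - cell$bg_mean_mu) +
          rep_len(cell$matching_offset, 3) + eps
        bc <- max(200, rnorm(1, cell$band_contrast_mu,
                             cell$band_contrast_sd))
        bp <- cell$band_period * exp(rnorm(1, 0, cell$band_period_jitter))
        axes <- cell$axes_mu * runif(2, 1 - cell$axes_jitter,
                                     1 + cell$axes_jitter)
        list(bg_mean = bg_mean, off = off, bc = bc, bp = bp, axes = axes,
             scn_seed = sample.int(2147483646L, 1))
      })
    })
    for (i in seq_len(cell$n)) {
      drawn <- cell_draws[[i]]
      scn_seed <- drawn$scn_seed
      sspec <- scene_spec(
        image_size = spec$image_size, pixels_per_mm = spec$pixels_per_mm,
        bg_period = spec$bg_period, bg_contrast = spec$bg_contrast,
        bg_mean = drawn$bg_mean, target_axes = drawn$axes,
        band_period = drawn$bp, band_contrast = drawn$bc,
        band_count_diversity = cell$band_count,
        disruption = cell$disruption, matching_offset = drawn$off,
        noise_sd = cell$noise_sd, seed = scn_seed)
      scene <- generate_scene(sspec)
      id <- sprintf("%s_%s_%03d", cell$species, cell$sex, i)
      scenes[[id]] <- scene
      truth[[id]] <- data.frame(
        id = id, species = cell$species, sex = cell$sex, seed = scn_seed,
        band_period = drawn$bp, band_contrast = drawn$bc,
        band_count = cell$band_count, disruption = cell$disruption,
        bg_period = spec$bg_period,
        target_mean_R = scene$truth$target_mean[["R"]],
        target_mean_G = scene$truth$target_mean[["G"]],
        target_mean_B = scene$truth$target_mean[["B"]],
        bg_mean_R = drawn$bg_mean[[1]], bg_mean_G = drawn$bg_mean[[2]],
        bg_mean_B = drawn$bg_mean[[3]])
      if (!is.null(write_dir)) write_scene(scene, write_dir, id)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  if (!is.null(write_dir))
    write.csv(truth, file.path(write_dir, "truth.csv"), row.names = FALSE)
  list(scenes = scenes, truth = truth, spec = spec)
}

#' Preset cohort mimicking the field study's qualitative contrasts
#'
#' Two synthetic "species" by two sexes. Males get higher marking
#' contrast, more boundary-crossing (disruptive) texture, and a
#' background-tracking deficit in the red channel (tracking slope well
#' below 1 plus a mean offset); females match their backgrounds closely
#' with weak disruption. Species differ in marking period and overall
#' disruption. Cell sizes default to 35/44 (species A females/males) and
#' 42/43 (species B).
#'
#' @param master_seed integer master seed.
#' @param n_per_cell optional single n overriding all four cell sizes
#'   (smaller cohorts for quick runs).
#' @param image_size scene side in px.
#' @param effects `"full"` for the preset contrasts, `"none"` to zero all
#'   group differences (null cohort for calibration of the statistics).
#' @return a [cohort_spec()].
#' @export
paper_mimic_cohort <- function(master_seed = 1L, n_per_cell = NULL,
                               image_size = 160,
                               effects = c("full", "none")) {
  effects <- match.arg(effects)
  ns <- if (is.null(n_per_cell)) c(35L, 44L, 42L, 43L) else
    rep(as.integer(n_per_cell), 4)
  if (effects == "none") {
    cells <- list(
      list(species = "A", sex = "female", n = ns[1]),
      list(species = "A", sex = "male", n = ns[2]),
      list(species = "B", sex = "female", n = ns[3]),
      list(species = "B", sex = "male", n = ns[4]))
    return(cohort_spec(cells, master_seed = master_seed,
                       image_size = image_size,
                       defaults = list(disruption = 0.3,
                                       band_contrast_mu = 2400)))
  }
  cells <- list(
    list(species = "A", sex = "female", n = ns[1], band_period = 8,
         band_contrast_mu = 1800, band_count = 2L, disruption = 0.08,
         matching_slope = c(1, 1, 1), matching_offset = c(0, 0, 0),
         matching_resid_sd = 150),
    list(species = "A", sex = "male", n = ns[2], band_period = 8,
         band_contrast_mu = 3200, band_count = 1L, disruption = 0.6,
         matching_slope = c(0.45, 1, 1),
         matching_offset = c(1500, 600, 400)),
    list(species = "B", sex = "female", n = ns[3], band_period = 12,
         band_contrast_mu = 2000, band_count = 2L, disruption = 0.16,
         matching_slope = c(1, 1, 1), matching_offset = c(0, 0, 0),
         matching_resid_sd = 150),
    list(species = "B", sex = "male", n = ns[4], band_period = 12,
         band_contrast_mu = 3400, band_count = 1L, disruption = 0.68,
         matching_slope = c(0.45, 1, 1),
         matching_offset = c(1500, 600, 400)))
  # natural backgrounds vary mostly in lightness; chromatic spread is
  # secondary, so channel means co-vary strongly across sites
  cohort_spec(cells, master_seed = master_seed, image_size = image_size,
              defaults = list(bg_chroma_sd = 250))
}
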