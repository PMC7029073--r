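# Image containers, gray-standard calibration and scene I/O.

#' Linear raw image
#'
#' A three-channel linear sensor image prior to reflectance calibration.
#' Channels are numeric matrices sharing dimensions; values must lie within
#' the stated bit depth.
#'
#' @param R,G,B numeric matrices of linear sensor values.
#' @param bit_depth 8 or 16.
#' @param pixels_per_mm positive spatial resolution.
#' @return an object of class `cq_raw`.
#' @export
raw_image <- function(R, G, B, bit_depth = 16, pixels_per_mm = 17) {
  chans <- list(R = R, G = G, B = B)
  dims <- lapply(chans, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stopf("all channels must share dimensions")
  if (!bit_depth %in% c(8, 16)) stopf("bit_depth must be 8 or 16")
  if (!is_scalar_num(pixels_per_mm) || pixels_per_mm <= 0)
    stopf("pixels_per_mm must be a positive number")
  top <- 2^bit_depth - 1
  rng <- range(unlist(lapply(chans, range)))
  if (rng[1] < 0 || rng[2] > top)
    stopf("pixel values outside [0, %d] for bit depth %d", top, bit_depth)
  structure(list(R = R, G = G, B = B, bit_depth = bit_depth,
                 pixels_per_mm = pixels_per_mm),
            class = "cq_raw")
}

#' Calibrated multispectral reflectance stack
#'
#' R/G/B reflectance planes on the 16-bit scale (0 = black, 65535 = perfect
#' diffuse reflector), with spatial resolution metadata.
#'
#' @param R,G,B numeric matrices of reflectance on `[0, 65535]`.
#' @param pixels_per_mm positive spatial resolution.
#' @return an object of class `cq_stack`.
#' @export
mspec_stack <- function(R, G, B, pixels_per_mm = 17) {
  chans <- list(R = R, G = G, B = B)
  dims <- lapply(chans, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stopf("all channels must share dimensions")
  if (!is_scalar_num(pixels_per_mm) || pixels_per_mm <= 0)
    stopf("pixels_per_mm must be a positive number")
  rng <- range(unlist(lapply(chans, range)))
  if (rng[1] < -1e-9 || rng[2] > REFL_MAX + 1e-9)
    stopf("reflectance values outside [0, %d]", REFL_MAX)
  structure(list(R = R, G = G, B = B, pixels_per_mm = pixels_per_mm),
            class = "cq_stack")
}

#' @export
print.cq_stack <- function(x, ...) {
  cat(sprintf("<cq_stack %d x %d px, %.3g px/mm>\n",
              nrow(x$R), ncol(x$R), x$pixels_per_mm))
  invisible(x)
}

#' Region mask
#'
#' Boolean raster the same shape as its image, labelling either the target
#' (animal dorsal surface) or the adjacent background patch.
#'
#' @param mask logical matrix; `TRUE` = inside the region.
#' @param role `"target"` or `"background"`.
#' @return an object of class `cq_mask` (a logical matrix with a `role`
#'   attribute).
#' @export
region_mask <- function(mask, role = c("target", "background")) {
  role <- match.arg(role)
  if (!is.matrix(mask)) stopf("mask must be a matrix")
  mask <- mask != 0
  if (!any(mask)) stopf("mask has no interior pixels")
  structure(mask, role = role, class = c("cq_mask", class(mask)))
}

mask_role <- function(mask) attr(mask, "role")

check_mask_fits <- function(mask, mat) {
  if (!identical(dim(mask), dim(mat)))
    stopf("mask dimensions (%d x %d) do not match image (%d x %d)",
          nrow(mask), ncol(mask), nrow(mat), ncol(mat))
  invisible(TRUE)
}

#' Gray standard set
#'
#' Regions of known diffuse reflectance used to standardise an image across
#' lighting conditions. At least two patches with distinct reflectances are
#' required to fix the calibration line.
#'
#' @param masks list of logical matrices, one per patch.
#' @param reflectances known reflectance fractions in `[0, 1]`, one per patch.
#' @return an object of class `cq_graystd`.
#' @export
gray_standard_set <- function(masks, reflectances) {
  if (length(masks) != length(reflectances))
    stopf("one reflectance per patch mask required")
  if (length(masks) < 2) stopf("at least 2 gray standard patches required")
  if (any(reflectances < 0 | reflectances > 1))
    stopf("known reflectances must be fractions in [0, 1]")
  overlap <- Reduce(`+`, lapply(masks, function(m) m != 0))
  if (any(overlap > 1)) stopf("gray standard patch regions must be disjoint")
  structure(list(masks = lapply(masks, function(m) m != 0),
                 reflectances = as.numeric(reflectances)),
            class = "cq_graystd")
}

#' Measure gray-standard patches on a raw image
#'
#' @param raw a [raw_image()].
#' @param standards a [gray_standard_set()].
#' @return matrix of per-patch, per-channel mean raw values
#'   (`length(patches)` rows, columns R, G, B).
#' @export
measure_gray_patches <- function(raw, standards) {
  stopifnot(inherits(raw, "cq_raw"), inherits(standards, "cq_graystd"))
  out <- vapply(standards$masks, function(m) {
    check_mask_fits(m, raw$R)
    c(mean(raw$R[m]), mean(raw$G[m]), mean(raw$B[m]))
  }, numeric(3))
  t(matrix(out, nrow = 3, dimnames = list(CHANNELS, NULL)))
}

#' Fit the gray-standard calibration line
#'
#' Fits, per channel, the least-squares line mapping measured linear sensor
#' values of the gray patches to their known reflectance expressed on the
#' 16-bit scale (`reflectance * 65535`). With exactly two patches the line
#' interpolates both exactly (two-point normalisation).
#'
#' @param measured per-patch per-channel mean raw values: a numeric matrix
#'   with one row per patch and columns R, G, B (a plain vector is recycled
#'   across the three channels).
#' @param known known reflectance fractions in `[0, 1]`, one per patch.
#' @return an object of class `cq_calibration` with per-channel `gain` and
#'   `offset`, mapping raw -> reflectance as `gain * raw + offset`.
#' @export
fit_gray_calibration <- function(measured, known) {
  if (is.null(dim(measured)))
    measured <- matrix(measured, ncol = 3, nrow = length(measured),
                       dimnames = list(NULL, CHANNELS))
  n <- nrow(measured)
  if (n < 2 || length(known) != n)
    stopf("calibration-degenerate: need >= 2 gray patches with known reflectances")
  target <- known * REFL_MAX
  gain <- offset <- setNames(numeric(3), CHANNELS)
  for (j in seq_along(CHANNELS)) {
    m <- measured[, j]
    if (max(m) - min(m) < 1e-12) {
      if (max(target) - min(target) < 1e-12) {
        stopf("calibration-degenerate: patches are indistinguishable")
      }
      stopf("calibration-degenerate: identical measured values for differing reflectances")
    }
    cf <- coef(lm(target ~ m))
    gain[j] <- cf[[2]]
    offset[j] <- cf[[1]]
  }
  if (any(gain <= 0))
    stopf("calibration-degenerate: non-positive gain (reflectance decreasing in sensor value)")
  structure(list(gain = gain, offset = offset), class = "cq_calibration")
}

#' Apply a calibration map to a raw image
#'
#' Transforms each channel by its calibration line and clips the result to
#' the 16-bit reflectance scale `[0, 65535]`. Overexposed pixels therefore
#' saturate rather than wrap. Resolution metadata is preserved.
#'
#' @param raw a [raw_image()].
#' @param map a [fit_gray_calibration()] result.
#' @return a [mspec_stack()].
#' @export
apply_calibration <- function(raw, map) {
  stopifnot(inherits(raw, "cq_raw"), inherits(map, "cq_calibration"))
  chans <- lapply(CHANNELS, function(ch) {
    v <- map$gain[[ch]] * raw[[ch]] + map$offset[[ch]]
    pmin(pmax(v, 0), REFL_MAX)
  })
  mspec_stack(chans[[1]], chans[[2]], chans[[3]],
              pixels_per_mm = raw$pixels_per_mm)
}

#' Resample a stack to a working spatial resolution
#'
#' Bilinear resampling by the factor `target_ppmm / pixels_per_mm`. The
#' standard working resolution is 17 pixels per mm. Upsampling (factor > 1)
#' is performed with a warning, since it fabricates no detail.
#'
#' @param x a [mspec_stack()] or a single numeric matrix.
#' @param target_ppmm desired resolution in pixels per mm.
#' @return same type as `x`, resampled, with updated metadata.
#' @export
rescale_to_resolution <- function(x, target_ppmm) {
  if (!is_scalar_num(target_ppmm) || target_ppmm <= 0)
    stopf("target_ppmm must be positive")
  stopifnot(inherits(x, "cq_stack"))
  factor <- target_ppmm / x$pixels_per_mm
  if (factor > 1 + 1e-12)
    warnf("upsampling by factor %.3g; no detail is gained", factor)
  if (abs(factor - 1) < 1e-12) {
    x$pixels_per_mm <- target_ppmm
    return(x)
  }
  w <- max(2L, round(nrow(x$R) * factor))
  h <- max(2L, round(ncol(x$R) * factor))
  chans <- lapply(CHANNELS, function(ch) {
    m <- EBImage::resize(EBImage::Image(x[[ch]]), w = w, h = h)
    pmin(pmax(EBImage::imageData(m), 0), REFL_MAX)
  })
  mspec_stack(chans[[1]], chans[[2]], chans[[3]], pixels_per_mm = target_ppmm)
}

# ---------------------------------------------------------------------------
# Scene I/O: 16-bit TIFF / PNG images, PNG masks, YAML annotations.

read_image_channels <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.tiff?$", lower)) {
    a <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(a, "bits.per.sample")
    if (is.null(bits)) bits <- 16L
    a <- round(a * (2^bits - 1)) # back to the stored integer scale
  } else if (grepl("\\.png$", lower)) {
    a <- png::readPNG(path)
    info <- attr(a, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 16L
    a <- a * (2^bits - 1)
  } else {
    stopf("unsupported image format: %s", path)
  }
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
  if (dim(a)[3] < 3) stopf("expected an RGB image: %s", path)
  list(R = a[, , 1], G = a[, , 2], B = a[, , 3], bit_depth = as.integer(bits))
}

read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  a > 0
}

#' Load a scene bundle from disk
#'
#' Reads an image (PNG or TIFF, 8- or 16-bit RGB), its region masks
#' (single-channel PNG, nonzero = inside) and a YAML annotation giving each
#' mask's role, the gray-patch rectangles with known reflectances, and the
#' spatial resolution.
#'
#' @param image_path path to the scene image.
#' @param mask_paths named or unnamed character vector of mask PNG paths;
#'   order must match the `masks` entries of the annotation.
#' @param annotation_path path to the YAML annotation.
#' @return list with elements `raw` ([raw_image()]), `masks` (list of
#'   [region_mask()]), `standards` ([gray_standard_set()]).
#' @export
load_scene <- function(image_path, mask_paths, annotation_path) {
  for (p in c(image_path, mask_paths, annotation_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  ann <- yaml::read_yaml(annotation_path)
  img <- read_image_channels(image_path)
  ppmm <- if (!is.null(ann$pixels_per_mm)) ann$pixels_per_mm else 17
  raw <- raw_image(img$R, img$G, img$B, bit_depth = img$bit_depth,
                   pixels_per_mm = ppmm)
  roles <- vapply(ann$masks, function(m) as.character(m$role), character(1))
  bad <- setdiff(roles, c("target", "background"))
  if (length(bad))
    stopf("unknown mask role '%s' in %s", bad[1], annotation_path)
  if (length(mask_paths) != length(roles))
    stopf("annotation lists %d masks but %d mask files given",
          length(roles), length(mask_paths))
  masks <- vector("list", length(roles))
  for (i in seq_along(roles)) {
    m <- read_mask_png(mask_paths[[i]])
    check_mask_fits(m, raw$R)
    masks[[i]] <- region_mask(m, roles[i])
  }
  names(masks) <- roles
  pm <- lapply(ann$gray_patches, function(p) {
    r <- as.integer(p$rect) # r0, c0, size (1-based, inclusive)
    m <- matrix(FALSE, nrow(raw$R), ncol(raw$R))
    m[r[1]:(r[1] + r[3] - 1L), r[2]:(r[2] + r[3] - 1L)] <- TRUE
    m
  })
  refl <- vapply(ann$gray_patches, function(p) as.numeric(p$reflectance),
                 numeric(1))
  list(raw = raw, masks = masks,
       standards = gray_standard_set(pm, refl))
}

#' Write a generated scene bundle to disk
#'
#' Writes the raw image as 16-bit TIFF, the masks as PNGs, and a YAML
#' annotation, in the layout [load_scene()] reads back.
#'
#' @param scene a [generate_scene()] result.
#' @param dir output directory (created if needed).
#' @param id basename stem for the files.
#' @return invisibly, the annotation path.
#' @export
write_scene <- function(scene, dir, id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  top <- 2^scene$raw$bit_depth - 1
  arr <- array(0, c(dim(scene$raw$R), 3L))
  # pre-round so the stored integers equal round(raw) exactly
  for (j in 1:3) arr[, , j] <- round(scene$raw[[CHANNELS[j]]]) / top
  img_path <- file.path(dir, paste0(id, ".tif"))
  tiff::writeTIFF(pmin(pmax(arr, 0), 1), img_path,
                  bits.per.sample = if (top > 255) 16L else 8L,
                  compression = "none")
  mask_paths <- character(0)
  ann_masks <- list()
  for (m in scene$masks) {
    mp <- file.path(dir, paste0(id, "_mask_", mask_role(m), ".png"))
    png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), mp)
    mask_paths <- c(mask_paths, mp)
    ann_masks[[length(ann_masks) + 1L]] <-
      list(file = basename(mp), role = mask_role(m))
  }
  ann <- list(
    pixels_per_mm = scene$raw$pixels_per_mm,
    bit_depth = scene$raw$bit_depth,
    masks = ann_masks,
    gray_patches = scene$patch_annotations
  )
  ann_path <- file.path(dir, paste0(id, ".yaml"))
  yaml::write_yaml(ann, ann_path)
  invisible(ann_path)
}

#' Write / read a reflectance stack as 16-bit TIFF
#'
#' Values are rounded to integers on the 16-bit scale; the round trip is
#' exact after that rounding.
#'
#' @param stack a [mspec_stack()].
#' @param path output `.tif` path.
#' @return `write_stack_tiff`: invisibly, `path`.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "cq_stack"))
  arr <- array(0, c(dim(stack$R), 3L))
  for (j in 1:3) arr[, , j] <- round(stack[[CHANNELS[j]]]) / REFL_MAX
  tiff::writeTIFF(pmin(pmax(arr, 0), 1), path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param pixels_per_mm resolution metadata to attach on read.
#' @return `read_stack_tiff`: a [mspec_stack()].
#' @export
read_stack_tiff <- function(path, pixels_per_mm = 17) {
  a <- round(tiff::readTIFF(path) * REFL_MAX)
  mspec_stack(a[, , 1], a[, , 2], a[, , 3], pixels_per_mm = pixels_per_mm)
}
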