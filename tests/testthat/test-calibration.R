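# Gray-standard calibration, image containers and scene I/O.

test_that("two-point calibration interpolates the standards exactly", {
  map <- fit_gray_calibration(c(100, 200), known = c(0.10, 0.20))
  expect_equal(unname(map$gain), rep(65.535, 3))
  expect_equal(unname(map$offset), rep(0, 3), tolerance = 1e-9)

  # arbitrary two-point line: must pass through both standards
  map2 <- fit_gray_calibration(c(40, 400), known = c(0.05, 0.80))
  expect_equal(map2$gain[["R"]] * 40 + map2$offset[["R"]], 0.05 * 65535)
  expect_equal(map2$gain[["R"]] * 400 + map2$offset[["R"]], 0.80 * 65535)
})

test_that("degenerate standards are rejected", {
  expect_error(fit_gray_calibration(c(50, 50), known = c(0.1, 0.2)),
               "calibration-degenerate")
  expect_error(fit_gray_calibration(matrix(100, 1, 3), known = 0.5),
               "calibration-degenerate")
})

test_that("multi-patch fit matches the normal-equations oracle", {
  measured <- c(100, 200, 300, 405) # three on a line, one perturbed
  known <- c(0.1, 0.2, 0.3, 0.4)
  map <- fit_gray_calibration(measured, known)
  X <- cbind(1, measured)
  beta <- solve(t(X) %*% X, t(X) %*% (known * 65535))
  expect_equal(map$offset[["G"]], beta[1], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(map$gain[["G"]], beta[2], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("apply_calibration clips, preserves identity and is monotone", {
  raw <- raw_image(matrix(1000, 4, 4), matrix(500, 4, 4), matrix(0, 4, 4),
                   bit_depth = 16, pixels_per_mm = 17)
  hot <- fit_gray_calibration(c(100, 200), known = c(0.1, 0.2)) # gain 65.5
  st <- apply_calibration(raw, hot)
  expect_equal(st$R[1, 1], 65535) # clipped at the scale top
  expect_equal(st$pixels_per_mm, 17)

  ident <- fit_gray_calibration(c(0, 65535), known = c(0, 1))
  vals <- matrix(c(0, 123.4, 40000, 65535), 2, 2)
  st2 <- apply_calibration(raw_image(vals, vals, vals), ident)
  expect_equal(st2$G, vals)

  # monotone per channel for any positive-gain map
  for (i in 1:20) {
    u <- runif(1, 0, 60000)
    v <- u + runif(1, 0, 5000)
    m <- matrix(c(u, v, u, v), 2, 2)
    stm <- apply_calibration(raw_image(m, m, m), hot)
    expect_true(stm$R[1, 1] <= stm$R[2, 1])
  }
})

test_that("a full-reflectance standard calibrates to the scale maximum", {
  spec <- scene_spec(gray_reflectances = c(0.2, 0.5, 1.0), noise_sd = 0,
                     seed = 11)
  sc <- generate_scene(spec)
  map <- fit_gray_calibration(measure_gray_patches(sc$raw, sc$standards),
                              sc$standards$reflectances)
  st <- apply_calibration(sc$raw, map)
  white <- sc$standards$masks[[3]]
  expect_equal(mean(st$R[white]), 65535, tolerance = 0.5 / 65535)
  expect_equal(mean(st$B[white]), 65535, tolerance = 0.5 / 65535)
})

test_that("calibrating generator scenes recovers the sensor line", {
  sc <- generate_scene(scene_spec(noise_sd = 0, seed = 3))
  map <- fit_gray_calibration(measure_gray_patches(sc$raw, sc$standards),
                              sc$standards$reflectances)
  truth <- sc$truth$calibration
  expect_equal(unname(map$gain), unname(truth$gain), tolerance = 1e-6)
  expect_equal(unname(map$offset), unname(truth$offset), tolerance = 1e-6)

  # with sensor noise the recovered gains stay consistent: bias shrinks
  # as the patch area grows
  errs <- vapply(c(8, 24), function(ps) {
    scn <- generate_scene(scene_spec(image_size = 192, patch_size = ps,
                                     noise_sd = 150, seed = 5))
    m <- fit_gray_calibration(measure_gray_patches(scn$raw, scn$standards),
                              scn$standards$reflectances)
    max(abs(m$gain - truth$gain) / truth$gain)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.02)
})

test_that("rescaling halves dimensions, keeps constants and warns upward", {
  st <- toy_stack(40, 40, matrix(5000, 40, 40), ppmm = 34)
  half <- rescale_to_resolution(st, 17)
  expect_equal(dim(half$R), c(20, 20))
  expect_equal(half$pixels_per_mm, 17)
  expect_true(all(abs(half$R - 5000) < 1e-6)) # constant preserved

  same <- rescale_to_resolution(st, 34)
  expect_identical(same$R, st$R)

  expect_warning(rescale_to_resolution(st, 68), "upsampling")
})

test_that("16-bit TIFF round trip is exact after integer rounding", {
  vals <- matrix(runif(64, 0, 65535), 8, 8)
  st <- mspec_stack(vals, vals / 2, vals / 3, pixels_per_mm = 17)
  path <- tempfile(fileext = ".tif")
  write_stack_tiff(st, path)
  back <- read_stack_tiff(path)
  expect_equal(back$R, round(st$R), ignore_attr = TRUE)
  expect_equal(back$G, round(st$G), ignore_attr = TRUE)
  expect_equal(back$B, round(st$B), ignore_attr = TRUE)
})

test_that("scene write/load round trip preserves the bundle", {
  sc <- generate_scene(scene_spec(seed = 9))
  dir <- tempfile("scenes")
  write_scene(sc, dir, "A_female_001")
  loaded <- load_scene(file.path(dir, "A_female_001.tif"),
                       c(file.path(dir, "A_female_001_mask_target.png"),
                         file.path(dir, "A_female_001_mask_background.png")),
                       file.path(dir, "A_female_001.yaml"))
  expect_equal(loaded$raw$R, round(sc$raw$R), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(unclass(loaded$masks$target),
               unclass(sc$masks$target), ignore_attr = TRUE)
  expect_equal(loaded$standards$reflectances, sc$standards$reflectances)
  expect_equal(loaded$raw$pixels_per_mm, 17)
})

test_that("scene loading rejects malformed inputs", {
  sc <- generate_scene(scene_spec(seed = 9))
  dir <- tempfile("scenes")
  write_scene(sc, dir, "s1")
  ann <- file.path(dir, "s1.yaml")
  img <- file.path(dir, "s1.tif")
  masks <- c(file.path(dir, "s1_mask_target.png"),
             file.path(dir, "s1_mask_background.png"))

  expect_error(load_scene("no_such.tif", masks, ann), "not found")

  # wrong-shaped mask
  bad_mask <- file.path(dir, "bad.png")
  png::writePNG(matrix(1, 10, 10), bad_mask)
  expect_error(load_scene(img, c(bad_mask, masks[2]), ann),
               "dimensions")

  # unknown role
  y <- yaml::read_yaml(ann)
  y$masks[[1]]$role <- "leg"
  bad_ann <- file.path(dir, "bad.yaml")
  yaml::write_yaml(y, bad_ann)
  expect_error(load_scene(img, masks, bad_ann), "unknown mask role")
})
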