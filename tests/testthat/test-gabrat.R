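# GabRat edge disruption.

test_that("square mask tangents align with the sides", {
  m <- matrix(FALSE, 40, 40)
  m[11:30, 11:30] <- TRUE
  es <- extract_edge_samples(region_mask(m, "target"))
  # side centres, away from corners
  top <- es[es$row == 11 & es$col %in% 18:23, ]
  side <- es[es$col == 11 & es$row %in% 18:23, ]
  expect_true(all(pmin(top$angle, pi - top$angle) < 1e-6))
  expect_true(all(abs(side$angle - pi / 2) < 1e-6))
})

test_that("disc tangents match the analytic circle", {
  es <- extract_edge_samples(disc_mask(64, 20))
  ctr <- (64 + 1) / 2
  theta <- atan2(es$row - ctr, es$col - ctr)
  expected <- (theta + pi / 2) %% pi
  d <- abs(es$angle - expected) %% pi
  d <- pmin(d, pi - d)
  expect_lt(max(d), 0.1)
  expect_gte(nrow(es), 8)
})

test_that("tiny blobs are rejected", {
  m <- matrix(FALSE, 10, 10)
  m[5:6, 5:6] <- TRUE
  expect_error(extract_edge_samples(region_mask(m, "target")),
               "target-too-small")
})

test_that("edge energies match the direct-convolution oracle", {
  set.seed(8)
  img <- matrix(runif(64 * 64, 0, 100), 64, 64)
  for (ang in c(0, 0.4, pi / 2, 2.1)) {
    en <- gabor_edge_energies(img, row = 30, col = 33, angle = ang,
                              sigma = 4)
    # coherent carrier runs across the tangent, false carrier along it
    bin_ang <- (ceiling(ang / pi * 360) - 0.5) * pi / 360
    expect_equal(en[["E_coh"]],
                 oracle_gabor_energy(img, 30, 33, 4, bin_ang + pi / 2),
                 tolerance = 0.02)
    expect_equal(en[["E_false"]],
                 oracle_gabor_energy(img, 30, 33, 4, bin_ang),
                 tolerance = 0.02)
  }
})

test_that("a step edge is coherent; cross-stripes are false edges", {
  n <- 64
  step <- matrix(0, n, n)
  step[, 33:n] <- 1000 # vertical edge at col boundary, tangent angle pi/2
  en <- gabor_edge_energies(step, row = 32, col = 32, angle = pi / 2,
                            sigma = 5)
  expect_gt(en[["E_coh"]], 0)
  expect_lt(en[["E_false"]] / (en[["E_coh"]] + en[["E_false"]]), 0.05)

  # sinusoid of wavelength 2*sigma oriented across the edge
  rows <- matrix(rep(1:n, times = n), n)
  sine <- 1000 * sin(2 * pi * rows / 10)
  en2 <- gabor_edge_energies(sine, row = 32, col = 32, angle = pi / 2,
                             sigma = 5)
  expect_gt(en2[["E_false"]], en2[["E_coh"]])
})

test_that("flat images give zero energies and GabRat zero", {
  img <- matrix(5, 64, 64)
  en <- gabor_edge_energies(img, 32, 32, pi / 4, sigma = 5)
  expect_equal(unname(en), c(0, 0), tolerance = 1e-6)
  expect_equal(gabrat_channel(img, disc_mask(64, 18), sigma = 5), 0)
})

test_that("a plain disc has a coherent outline; continuation raises GabRat", {
  n <- 96
  mask <- disc_mask(n, 22)
  dark <- matrix(1000, n, n)
  bright <- dark
  bright[unclass(mask)] <- 6000
  plain <- gabrat_channel(bright, mask, sigma = 5)
  expect_lt(plain, 0.1)

  # radial striping continuing across the outline
  ctr <- (n + 1) / 2
  phi <- atan2(matrix(rep(1:n, n), n) - ctr,
               matrix(rep(1:n, each = n), n) - ctr)
  striped <- bright + 2500 * cos(14 * phi)
  expect_gt(gabrat_channel(striped, mask, sigma = 5), plain)
})

test_that("GabRat stays within [0, 1] and averages channels", {
  set.seed(5)
  img <- matrix(runif(96 * 96, 0, 65535), 96, 96)
  mask <- disc_mask(96, 25)
  v <- gabrat_channel(img, mask, sigma = 5)
  expect_gte(v, 0)
  expect_lte(v, 1)

  st <- mspec_stack(img, img, img)
  gr <- gabrat_mean(st, mask, sigma = 5)
  expect_equal(gr$mean_gabrat, v, tolerance = 1e-12)
  expect_equal(unname(gr$per_channel), rep(v, 3), tolerance = 1e-12)
  expect_equal(mean(c(0.1, 0.2, 0.3)), 0.2) # mean_gabrat definition
  expect_equal(gr$mean_gabrat, mean(gr$per_channel))
})

test_that("GabRat is invariant to gain and offset", {
  set.seed(6)
  img <- matrix(runif(80 * 80, 0, 1000), 80, 80)
  mask <- disc_mask(80, 20)
  base <- gabrat_channel(img, mask, sigma = 5)
  trans <- gabrat_channel(3.7 * img + 1234, mask, sigma = 5)
  expect_equal(trans, base, tolerance = 1e-8)
})

test_that("GabRat is stable under 90-degree rotation", {
  sc <- generate_scene(scene_spec(seed = 21, disruption = 0.4,
                                  band_angle = 0.7))
  map <- fit_gray_calibration(measure_gray_patches(sc$raw, sc$standards),
                              sc$standards$reflectances)
  st <- apply_calibration(sc$raw, map)
  mask <- sc$masks$target
  v1 <- gabrat_channel(st$R, mask, sigma = 5)
  rot <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  v2 <- gabrat_channel(rot(st$R), region_mask(rot(unclass(mask)), "target"),
                       sigma = 5)
  expect_lt(abs(v1 - v2), 0.02)
})

test_that("GabRat rises with the generator's disruption parameter", {
  vals <- vapply(c(0, 0.5, 1), function(d) {
    mean(vapply(1:3, function(s) {
      sc <- generate_scene(scene_spec(seed = 400 + s, disruption = d))
      map <- fit_gray_calibration(
        measure_gray_patches(sc$raw, sc$standards),
        sc$standards$reflectances)
      st <- apply_calibration(sc$raw, map)
      gabrat_mean(st, sc$masks$target)$mean_gabrat
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("disruption classes follow the published cutoffs", {
  expect_equal(classify_disruption(0.5), "high")
  expect_equal(classify_disruption(0.1), "low")
  expect_equal(classify_disruption(0.3), "intermediate")
  expect_equal(classify_disruption(0.4), "intermediate") # boundary excluded
  expect_error(classify_disruption(1.2), "\\[0, 1\\]")
})
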