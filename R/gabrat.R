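# GabRat edge-disruption metric.
#
# For every pixel on the target outline, a quadrature pair of Gabor filters
# is evaluated at two orientations: carrier across the outline (stripes
# parallel to the local tangent), which responds to the coherent body edge,
# and carrier along the outline, which responds to false edges running into
# the background. GabRat is the mean over outline pixels of
# E_false / (E_false + E_coh), bounded in [0, 1] by construction. Values
# above 0.4 indicate strong edge disruption; below 0.2, weak.

#' Extract outline samples with local tangent angles
#'
#' Boundary pixels are mask pixels with at least one of their 8 neighbours
#' outside the mask. The tangent at each boundary pixel is perpendicular to
#' the gradient of the Gaussian-smoothed (sigma = 2 px) mask indicator, so
#' texture inside or outside the target cannot corrupt the outline
#' orientation estimate.
#'
#' @param mask a [region_mask()] or logical matrix with a single connected
#'   target region of at least 8 boundary pixels.
#' @param smooth_sigma smoothing scale for the orientation estimate (px).
#' @return data.frame with columns `row`, `col`, `angle` (tangent angle in
#'   `[0, pi)`).
#' @export
extract_edge_samples <- function(mask, smooth_sigma = 2) {
  m <- mask != 0
  if (!any(m)) stopf("target-too-small: empty mask")
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  if (max(lab) != 1)
    stopf("mask must contain exactly one connected target region (found %d)",
          max(lab))
  nr <- nrow(m); nc <- ncol(m)
  # pad with FALSE so border pixels count as boundary
  pm <- matrix(FALSE, nr + 2L, nc + 2L)
  pm[2:(nr + 1L), 2:(nc + 1L)] <- m
  inside8 <- pm[2:(nr + 1L), 2:(nc + 1L)]
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    inside8 <- inside8 & pm[(2 + dr):(nr + 1L + dr), (2 + dc):(nc + 1L + dc)]
  }
  boundary <- m & !inside8
  idx <- which(boundary, arr.ind = TRUE)
  if (nrow(idx) < 8) stopf("target-too-small: fewer than 8 boundary pixels")
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(m * 1),
                                          sigma = smooth_sigma))
  rr <- idx[, 1]; cc <- idx[, 2]
  r0 <- pmax(rr - 1L, 1L); r1 <- pmin(rr + 1L, nr)
  c0 <- pmax(cc - 1L, 1L); c1 <- pmin(cc + 1L, nc)
  gy <- (sm[cbind(r1, cc)] - sm[cbind(r0, cc)]) / (r1 - r0)
  gx <- (sm[cbind(rr, c1)] - sm[cbind(rr, c0)]) / (c1 - c0)
  ang <- (atan2(gy, gx) + pi / 2) %% pi
  keep <- (gx^2 + gy^2) > 1e-12
  data.frame(row = rr[keep], col = cc[keep], angle = ang[keep])
}

# Quadrature Gabor kernel pair with carrier direction psi, wavelength
# lambda = 2*sigma, isotropic Gaussian envelope. The even kernel is
# mean-subtracted so both kernels have zero DC response (GabRat is then
# invariant to global gain and offset).
gabor_pair <- function(sigma, psi, radius = ceiling(3 * sigma)) {
  d <- (-radius):radius
  X <- matrix(rep(d, each = length(d)), length(d)) # column offsets (x)
  Y <- matrix(rep(d, times = length(d)), length(d)) # row offsets (y)
  env <- exp(-(X^2 + Y^2) / (2 * sigma^2))
  phase <- 2 * pi * (X * cos(psi) + Y * sin(psi)) / (2 * sigma)
  even <- env * cos(phase)
  even <- even - env * sum(even) / sum(env) # zero DC, envelope-shaped correction
  odd <- env * sin(phase)
  list(even = even, odd = odd, radius = radius)
}

reflect_pad <- function(mat, r) {
  nr <- nrow(mat); nc <- ncol(mat)
  ri <- c(pmin(r:1, nr), 1:nr, nr - pmin(1:r, nr - 1L) )
  ci <- c(pmin(r:1, nc), 1:nc, nc - pmin(1:r, nc - 1L) )
  mat[ri, ci, drop = FALSE]
}

# Cache of quantized-angle kernels, one entry per (sigma, bin).
kernel_cache <- new.env(parent = emptyenv())
N_ANGLE_BINS <- 360L

edge_kernels <- function(sigma, bin) {
  key <- sprintf("s%.6g_b%d", sigma, bin)
  k <- kernel_cache[[key]]
  if (is.null(k)) {
    ang <- (bin - 0.5) * pi / N_ANGLE_BINS
    coh <- gabor_pair(sigma, ang + pi / 2) # carrier across the outline
    fal <- gabor_pair(sigma, ang)          # carrier along the outline
    k <- list(ce = as.numeric(coh$even), co = as.numeric(coh$odd),
              fe = as.numeric(fal$even), fo = as.numeric(fal$odd),
              radius = coh$radius)
    kernel_cache[[key]] <- k
  }
  k
}

#' Gabor edge energies at one outline sample
#'
#' Quadrature (even + odd) Gabor energy at the sample position, wavelength
#' `2 * sigma`, at two orientations: carrier across the local tangent
#' (coherent edge energy) and along it (false edge energy). The image is
#' reflect-padded where the filter support leaves it.
#'
#' @param channel numeric matrix.
#' @param row,col sample position (matrix indices).
#' @param angle tangent angle in `[0, pi)`.
#' @param sigma Gabor scale in px.
#' @return named numeric vector `c(E_coh =, E_false =)`.
#' @export
gabor_edge_energies <- function(channel, row, col, angle, sigma = 5) {
  res <- gabrat_engine(channel,
                       data.frame(row = row, col = col, angle = angle),
                       sigma)
  c(E_coh = res$E_coh[1], E_false = res$E_false[1])
}

# Vectorised evaluation over all edge samples of one channel.
gabrat_engine <- function(channel, samples, sigma) {
  if (!is_scalar_num(sigma) || sigma <= 0) stopf("sigma must be positive")
  radius <- ceiling(3 * sigma)
  pad <- reflect_pad(channel, radius)
  nrp <- nrow(pad)
  d <- (-radius):radius
  # linear-index offsets of the kernel window within the padded matrix
  offs <- as.numeric(outer(d, d * nrp, `+`))
  bins <- pmin(pmax(1L, ceiling(samples$angle / pi * N_ANGLE_BINS)),
               N_ANGLE_BINS)
  n <- nrow(samples)
  E_coh <- E_false <- numeric(n)
  for (i in seq_len(n)) {
    centre <- (samples$row[i] + radius) + (samples$col[i] + radius - 1) * nrp
    patch <- pad[centre + offs]
    k <- edge_kernels(sigma, bins[i])
    E_coh[i] <- sqrt(sum(patch * k$ce)^2 + sum(patch * k$co)^2)
    E_false[i] <- sqrt(sum(patch * k$fe)^2 + sum(patch * k$fo)^2)
  }
  data.frame(E_coh = E_coh, E_false = E_false)
}

#' GabRat for a single channel
#'
#' Mean over outline pixels of `E_false / (E_false + E_coh)`. Samples where
#' both energies vanish (perfectly flat neighbourhood) are skipped; if every
#' sample is skipped the value is 0.
#'
#' @param channel numeric matrix.
#' @param mask target [region_mask()].
#' @param sigma Gabor scale in px (default 5, suited to images at 17
#'   px/mm).
#' @param samples optional precomputed [extract_edge_samples()] result.
#' @return GabRat value in `[0, 1]`.
#' @export
gabrat_channel <- function(channel, mask, sigma = 5, samples = NULL) {
  if (is.null(samples)) samples <- extract_edge_samples(mask)
  en <- gabrat_engine(channel, samples, sigma)
  tot <- en$E_coh + en$E_false
  # flat neighbourhoods give energies at floating-point noise level; treat
  # them as the zero case and skip them
  ok <- tot > 1e-9 * (1 + mean(abs(channel)))
  if (!any(ok)) return(0)
  mean(en$E_false[ok] / tot[ok])
}

#' Mean GabRat over the three channels
#'
#' Computes GabRat for the R, G and B reflectance planes and their
#' arithmetic mean.
#'
#' @param stack a [mspec_stack()].
#' @param mask target [region_mask()].
#' @param sigma Gabor scale in px.
#' @return an object of class `cq_gabrat`: list with `per_channel` (named
#'   vector), `mean_gabrat`, `sigma`, `n_edge`.
#' @export
gabrat_mean <- function(stack, mask, sigma = 5) {
  stopifnot(inherits(stack, "cq_stack"))
  check_mask_fits(mask, stack$R)
  samples <- extract_edge_samples(mask)
  per <- vapply(CHANNELS, function(ch)
    gabrat_channel(stack[[ch]], mask, sigma, samples = samples), numeric(1))
  structure(list(per_channel = per, mean_gabrat = mean(per),
                 sigma = sigma, n_edge = nrow(samples)),
            class = "cq_gabrat")
}

#' @export
print.cq_gabrat <- function(x, ...) {
  cat(sprintf(
    "<cq_gabrat mean %.3f (R %.3f, G %.3f, B %.3f), sigma %g, %d edge px>\n",
    x$mean_gabrat, x$per_channel[["R"]], x$per_channel[["G"]],
    x$per_channel[["B"]], x$sigma, x$n_edge))
  invisible(x)
}

#' Classify an edge-disruption value
#'
#' Values above 0.4 are considered highly disruptive and values below 0.2
#' weakly disruptive; the rest are intermediate.
#'
#' @param value GabRat value in `[0, 1]`.
#' @return `"low"`, `"intermediate"` or `"high"`.
#' @export
classify_disruption <- function(value) {
  if (!is_scalar_num(value) || value < 0 || value > 1)
    stopf("GabRat value must lie in [0, 1]")
  if (value > 0.4) "high" else if (value < 0.2) "low" else "intermediate"
}
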