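# Granularity analysis: band-pass energy spectrum of a region and the
# descriptors e_max, Filter_max, e_prop.
#
# "Energy" at a filter size is the standard deviation of the band-filtered
# pixel reflectance over the region. The filter bank is a geometric series
# of isotropic annular Fourier band-pass filters; with cutoffs at the
# geometric midpoints between neighbouring sizes the bands form an exact
# partition of the non-DC spectrum, so on a fully masked region the band
# variances sum to the total variance (Parseval).

#' Build a geometric filter bank
#'
#' Filter sizes are `min_size * factor^k` while they stay below
#' `max_size` (within floating-point slack). The standard bank runs from 2
#' to 256 px in multiples of sqrt(2), i.e. 15 sizes.
#'
#' @param min_size,max_size smallest and largest filter size in pixels.
#' @param factor ratio between consecutive sizes (> 1).
#' @return an object of class `cq_filter_bank`: a numeric vector of sizes
#'   with the growth `factor` as an attribute.
#' @export
build_filter_bank <- function(min_size = 2, max_size = 256, factor = sqrt(2)) {
  if (!is_scalar_num(min_size) || min_size <= 0 ||
      !is_scalar_num(max_size) || max_size < min_size)
    stopf("filter sizes must satisfy 0 < min_size <= max_size")
  if (!is_scalar_num(factor) || factor <= 1)
    stopf("size factor must exceed 1")
  k <- 0:ceiling(log(max_size / min_size, factor) + 1)
  sizes <- min_size * factor^k
  sizes <- sizes[sizes <= max_size * (1 + 1e-9)]
  structure(sizes, factor = factor, class = "cq_filter_bank")
}

#' Pattern channel: mean of red and green reflectance
#'
#' The luminance-like plane on which pattern (granularity) analysis runs.
#'
#' @param stack a [mspec_stack()].
#' @return numeric matrix, pixelwise `(R + G) / 2`.
#' @export
pattern_channel <- function(stack) {
  stopifnot(inherits(stack, "cq_stack"))
  (stack$R + stack$G) / 2
}

# Period (px) of each Fourier cell of an M x N grid; Inf at DC.
period_grid <- function(M, N) {
  fy <- fft_freq(M)
  fx <- fft_freq(N)
  r <- sqrt(outer(fy^2, fx^2, `+`))
  p <- 1 / r
  p[1, 1] <- Inf
  p
}

#' Band-pass energy spectrum of a masked region
#'
#' For each filter size, pixels outside the mask are filled with the masked
#' mean, the region is passed through an ideal isotropic annular Fourier
#' band-pass, and the energy is the standard deviation of the filtered
#' values over the masked pixels only. Pass-band cutoffs sit at the
#' geometric midpoints between neighbouring sizes (`size * sqrt(factor)`);
#' the outermost bands are open-ended (the smallest-size band reaches the
#' Nyquist corner, the largest reaches up to but excluding the DC term), so
#' the bank partitions the whole non-constant spectrum.
#'
#' @param channel numeric matrix (e.g. from [pattern_channel()]).
#' @param mask a [region_mask()] or logical matrix.
#' @param bank a [build_filter_bank()] result.
#' @param crop crop computation to the mask bounding box (default TRUE);
#'   filtering is then local to the region, which is faster and keeps the
#'   spectrum independent of unrelated image content.
#' @return an object of class `cq_energy_spectrum`: a data.frame with
#'   columns `size` and `energy`, carrying the bank `factor` attribute.
#' @export
bandpass_energy <- function(channel, mask, bank = build_filter_bank(),
                            crop = TRUE) {
  stopifnot(is.matrix(channel), inherits(bank, "cq_filter_bank"))
  mask <- mask != 0
  check_mask_fits(mask, channel)
  if (!any(mask)) stopf("region error: empty mask")
  if (crop) {
    rr <- range(which(rowSums(mask) > 0))
    cc <- range(which(colSums(mask) > 0))
    channel <- channel[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    mask <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  }
  if (nrow(channel) < 2 || ncol(channel) < 2)
    stopf("region error: bounding box must be at least 2 x 2")
  mu <- mean(channel[mask])
  filled <- channel
  filled[!mask] <- mu
  f <- fft(filled)
  P <- period_grid(nrow(filled), ncol(filled))
  g <- sqrt(attr(bank, "factor"))
  sizes <- as.numeric(bank)
  # band j passes periods [cut[j], cut[j+1]); outer bands open-ended
  cuts <- c(0, sizes[-length(sizes)] * g, Inf)
  nm <- length(filled)
  energies <- vapply(seq_along(sizes), function(j) {
    sel <- P >= cuts[j] & P < cuts[j + 1]
    if (!any(sel)) return(0)
    fb <- f
    fb[!sel] <- 0i
    band <- Re(fft(fb, inverse = TRUE)) / nm
    sd(band[mask])
  }, numeric(1))
  structure(data.frame(size = sizes, energy = energies),
            factor = attr(bank, "factor"),
            class = c("cq_energy_spectrum", "data.frame"))
}

#' Pattern descriptors from an energy spectrum
#'
#' Summarises an energy spectrum into the three standard descriptors:
#' `e_max`, the maximum energy (contrast of the dominant marking);
#' `filter_max`, the filter size where the maximum occurs (dominant marking
#' size; ties resolve to the smallest size); and `e_prop`, the maximum as a
#' proportion of the summed spectrum (inverse pattern diversity).
#' Log10 transforms of all three are included for group statistics.
#'
#' @param spectrum a [bandpass_energy()] result.
#' @return an object of class `cq_descriptors`: a one-row data.frame with
#'   columns `e_max`, `filter_max`, `e_prop` and their `log10_` versions.
#' @export
pattern_descriptors <- function(spectrum) {
  stopifnot(is.data.frame(spectrum),
            all(c("size", "energy") %in% names(spectrum)))
  e <- spectrum$energy
  if (all(e <= 0))
    stopf("undefined descriptors: all band energies are zero (constant region)")
  i <- which.max(e) # which.max takes the first index on ties = smallest size
  e_max <- e[i]
  filter_max <- spectrum$size[i]
  e_prop <- e_max / sum(e)
  structure(data.frame(e_max = e_max, filter_max = filter_max,
                       e_prop = e_prop,
                       log10_e_max = log10(e_max),
                       log10_filter_max = log10(filter_max),
                       log10_e_prop = log10(e_prop)),
            class = c("cq_descriptors", "data.frame"))
}
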