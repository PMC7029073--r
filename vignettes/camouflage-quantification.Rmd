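---
title: "Quantifying camouflage: calibration, pattern spectra, edge disruption and background matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying camouflage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camoquant)
```

`camoquant` measures two complementary camouflage strategies from
calibrated images of animals on their backgrounds: *background matching*
(resembling the background's colour) and *disruptive coloration*
(high-contrast markings that break up the body outline). This vignette is
the package's account of the methods: the models, the tunable parameters
and their defaults, the numerical choices, and what the synthetic scenes
validate — and what they do not.

## Reflectance calibration

Pipelines of this kind start from linear (gamma-free) images. Lighting
varies between photographs, so each image carries gray standard patches of
known diffuse reflectance. `fit_gray_calibration()` fits, per channel, the
least-squares line from measured patch means to known reflectance expressed
on the 16-bit scale (`reflectance × 65535`). With exactly two standards the
line interpolates both, which is the classic two-point normalisation; with
more it is an ordinary regression. Design choices:

- **Affine per-channel model.** Gray standards constrain gain and offset;
  anything richer (vignetting, spatial nonuniformity) is out of scope.
- **Clipping, not wraparound**, at `[0, 65535]`: field protocols expose to
  avoid saturation, so saturation is the correct failure mode for values
  beyond the scale.
- **Degenerate inputs** (fewer than two patches, or indistinguishable
  measured values with differing albedos) are errors, not warnings: a wrong
  calibration silently poisons every downstream statistic.

The working spatial resolution is **17 px/mm**; `rescale_to_resolution()`
resamples bilinearly, warning on upsampling (which fabricates no detail).

## Granularity analysis

Pattern is analysed on the mean of the red and green reflectance planes —
a luminance-like channel dominated by the wavelengths that textural
contrast lives in for this kind of imagery. The masked region is
decomposed with a bank of ideal isotropic annular Fourier band-pass
filters with sizes 2–256 px in multiples of √2 (15 sizes). The *energy*
at a size is the standard deviation of the band-filtered reflectance over
the masked pixels; the curve of energy against size is the energy
spectrum, summarised by `e_max` (contrast of the dominant marking),
`Filter_max` (its size), and `e_prop = e_max / Σ energies` (inverse
pattern diversity, in (0, 1]).

Numerical choices:

- **Pass-band cutoffs at geometric midpoints** between neighbouring sizes
  (`size × √√2`). The outermost bands are open-ended — the smallest-size
  band extends to the Nyquist corner and the largest up to (but excluding)
  the constant term — so the bank partitions the whole non-DC spectrum.
  On a fully masked rectangle the band variances therefore sum exactly to
  the region variance (Parseval), which the tests assert; hard outer
  cutoffs would silently discard the high-frequency corner of the
  discrete spectrum (about 5% of white-noise variance).
- **Mean-fill outside the mask** before the FFT, never zero-fill: filling
  with the masked mean avoids injecting a spurious step at the mask
  boundary. Statistics are then restricted to masked pixels.
- **Computation is cropped to the mask's bounding box**, making the
  spectrum independent of unrelated image content and faster.
- **Ties in `Filter_max` resolve to the smallest size**; an all-zero
  spectrum (constant region) is an error since the descriptors are
  undefined.
- **log10 transforms** of all three descriptors are carried alongside the
  raw values because group statistics on such descriptors are
  conventionally run on the log scale, where their distributions are far
  closer to normal.

## GabRat edge disruption

Disruptive markings defeat edge detectors. GabRat quantifies this with a
quadrature pair (even + odd) of Gabor filters evaluated at every outline
pixel of the target at two orientations: carrier *across* the local
tangent — responding to the coherent body edge — and carrier *along* it —
responding to "false" edges running over the outline into the background.
The per-pixel ratio `E_false / (E_false + E_coh)` is averaged along the
outline, per channel, and the three channels are averaged into X̄ GabRat.
The ratio construction bounds values to [0, 1]; by convention values
above 0.4 are highly disruptive and below 0.2 weakly so.

Parameters and choices:

- **σ = 5 px, λ = 2σ, isotropic envelope, support radius 3σ.** At the
  17 px/mm working scale this probes the spatial band a small-vertebrate
  viewer would use at naturalistic distances; σ is configurable.
- **Outline orientation comes from the Gaussian-smoothed (σ = 2 px) mask
  indicator**, not from the image, so internal texture cannot corrupt the
  tangent estimate.
- **Zero-mean filters.** The even Gabor has a small DC response which is
  removed with an envelope-shaped correction; GabRat is then exactly
  invariant to global gain and offset, which the tests assert.
- **Edge pixels whose total energy is at floating-point noise level are
  skipped** rather than scored 0 or 0.5, so flat scenes do not bias the
  average; if all pixels are skipped the value is 0.
- **Single perpendicular orientation for the false-edge energy.** A
  variant takes the maximum over many orientations; the single-orientation
  form is implemented and recorded in the run metadata.
- Tangent angles are quantized to 0.5° bins so the four kernels per bin
  can be cached; the discretisation error is far below the rotation
  tolerance (90° rotations move GabRat by < 0.02).

## Background matching

Across the individuals of a group, a well-matched animal's mean channel
reflectance should track its own background's one-to-one. Because both
variables are measured with error, an ordinary regression slope would be
attenuated; the package uses **major-axis (Type II) regression** — the
first principal axis of the bivariate covariance. The slope-vs-1 test is
the residual-vs-axis correlation test: at hypothesized slope $b_0$,
residual scores $y - b_0 x$ and axis scores $x + b_0 y$ are uncorrelated
iff $b_0$ is the fitted axis, and their correlation $r_s$ with
$df = n - 2$ is t-distributed under the hypothesis. Confidence limits for
β invert this test; in angle space the inversion has a closed form (with
eigenvalues $\lambda_1 \ge \lambda_2$ of the covariance matrix, the
critical angular offset is $\tfrac12 \arcsin\sqrt{s^2}$ with
$s^2 = \lambda_1\lambda_2 r_c^2 / (A(1-r_c^2))$,
$A = (\lambda_1-\lambda_2)^2/4$), so the interval covers $b_0$ exactly
when the test at $b_0$ is non-significant. Weakly determined axes yield
unbounded intervals, reported as ±Inf. Perfectly collinear data make the
residual variance zero; the convention $r_s = 0, p = 1$ applies (the data
sit on the hypothesized line).

Following the usual reporting rule, slope tests are flagged "reported"
only for groups whose regression correlation is itself significant;
a slope not different from 1 in a significant regression is the
background-matching verdict.

## Group statistics

Cohorts are species (2) × sex (2) and usually unbalanced, so ANOVAs and
MANOVA use **Type III sums of squares with sum-to-zero contrasts** (each
term adjusted for all others, the convention of the major commercial
packages); with balanced cells this reduces exactly to the classical
decomposition, which is tested. Wilks' λ = det(E)/det(E+H) per term with
Rao's F approximation; with a single response it reduces algebraically to
the univariate F. Tukey–Kramer comparisons use the studentized range with
harmonic-mean cell sizes and the error stratum of the full two-factor
model; compact letter displays are built greedily from maximal runs of
mutually non-significant groups ordered by mean. Paired t-tests compare
each animal with its own background patch on the log10 descriptors.
Degenerate paired comparisons (exactly constant differences) are reported
as NA rather than aborting a pipeline run.

## The synthetic scene generator

Every stage is validated against scenes with known truth
(`generate_scene()`, `generate_cohort()`):

- **Background**: band-limited Gaussian noise with a controllable dominant
  period and contrast, over per-channel mean reflectances.
- **Target**: an ellipse filled with sinusoidal bands — dominant period
  `band_period` (→ `Filter_max`), amplitude set by `band_contrast`
  (→ `e_max`), with `band_count_diversity` harmonically spaced components
  (→ `e_prop`). Matching bands **fade before the outline** (cosine ramp
  over ~6 px): markings that stop short of the body edge are the classic
  *background-matching* pattern, and without the ramp their terminations
  flood the edge detector and mask the disruption manipulation.
- **Disruption**: with weight `d ∈ [0, 1]`, radial stripes phase-continuous
  across the outline and oriented across it — precisely the image property
  GabRat detects. Their wavelength along the outline
  (`disruption_period`, default 10 px) is sized to the Gabor scale 2σ,
  because disruptive markings are effective relative to the viewer's
  acuity, not to the animal's interior pattern scale.
- **Matching**: the target mean is the background mean plus a per-channel
  offset; cohorts can additionally set a tracking slope per channel
  (`matching_slope`; 1 = perfect matching, values below 1 create the
  slope deficit a matching test should detect — a pure offset can only
  move the intercept).
- **Sensor model**: reflectance is pushed through a known per-channel
  affine sensor response and additive Gaussian noise *before* calibration,
  so calibration recovery is genuinely tested. Gray patches render in the
  corners.
- **Region masks**: the target ellipse, and a background annulus adjacent
  to it whose area matches the target area within 10%.
- **Seeding**: cohort parameters are drawn sequentially from one
  well-seeded stream per species×sex cell, and every scene receives an
  unrelated rendering seed from that stream. (An earlier splitter that
  derived per-scene seeds affinely from the scene index produced
  measurably correlated first draws across streams — enough to bias
  slope-test sizes — which is why the sequential design is used.)

The bundled `paper_mimic_cohort()` preset encodes the qualitative
structure reported for the motivating field system: males of both
synthetic species get higher marking contrast, strong boundary-crossing
texture, and a red-channel tracking deficit (slope 0.45 plus an offset);
females match their backgrounds with high fidelity (tracking slope 1,
zero offset, small shared luminance residual of 150 units) and carry weak
disruption. Backgrounds vary across individuals mainly through a shared
lightness factor (CV 0.15) with secondary chromatic spread (SD 250),
reflecting natural substrates whose colour varies mostly in lightness;
this also couples the three per-channel matching tests, which is what
makes "all three channel CIs cover 1" a stable property of matched
groups. Cell sizes default to 35/44/42/43.

## Problem sizes and validation scope

The test-suite and acceptance checks run on 160 px scenes with a
56 × 38 px target at 17 px/mm, cohorts of 8 per cell over 20 master
seeds, 100 randomized scenes for the GabRat range check, 40 + 50 scenes
for granularity recovery, and 500–1000 replicates for the null
calibrations of the slope test, ANOVA and paired t. These sizes were
chosen so the whole validation runs comfortably on a laptop while leaving
the statistical assertions well-powered; the full-size preset (164
scenes) runs through the identical code path.

What passing tests show — and what they do not: the synthetic scenes
demonstrate that each estimator recovers its own generating parameter
monotonically and that the statistics hold their nominal sizes. They do
not emulate real vegetation geometry, specular highlights, shadows,
demosaicing artefacts, or ultraviolet reflectance (the pipeline is
restricted to the visible RGB channels), and absolute synthetic GabRat
levels (~0.45–0.65) sit above typical field values (< 0.2) because a
mean-matched synthetic outline carries little coherent step energy;
conclusions about absolute disruption classes on real photographs should
not be calibrated against the synthetic scenes.

## Known limitations

- The calibration model is linear per channel; real sensors deviate at
  the extremes of their range.
- GabRat is computed at a single σ; multi-scale sweeps tuned to specific
  predator acuities are out of scope.
- The granularity bank is isotropic; orientation-resolved pattern
  analysis is not implemented.
- Published tables from field studies of this design report descriptor
  values whose scale conventions can be ambiguous (log vs raw); this
  package always reports both raw and log10 descriptors explicitly to
  avoid that ambiguity.
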