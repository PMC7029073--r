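Package: camoquant
Title: Quantitative Analysis of Animal Camouflage from Calibrated Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Measures camouflage of animals against their backgrounds from
    calibrated RGB reflectance images. Implements gray-standard reflectance
    calibration, granularity (band-pass energy spectrum) pattern analysis
    with the e_max, Filter_max and e_prop descriptors, the GabRat
    edge-disruption metric based on quadrature Gabor filters, colour
    background matching via major-axis (Type II) regression with tests of
    slope = 1, and the associated group statistics (two-factor MANOVA and
    ANOVA with Type III sums of squares, Tukey-Kramer comparisons, paired
    t-tests). Includes a synthetic-scene generator that renders banded
    elliptical targets on textured backgrounds with known ground truth, so
    the whole pipeline can be validated end to end without field
    photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    EBImage,
    jsonlite,
    png,
    tiff,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
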