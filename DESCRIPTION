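Package: pcparams
Title: Phase-Contrast Microscopy Parameters for Label-Free Tissue
    Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes five advanced phase-contrast microscopy parameters
    (refractive index variance, scattering coefficient, anisotropy factor,
    fractal dimension and outer scale) from phase images of thin tissue
    slices, screens them for healthy-versus-tumoral significance with
    one-way ANOVA, and benchmarks eight classifiers with re-substitution
    and cross-validation error decomposed into false-positive and
    false-negative rates. Includes a synthetic phantom generator (Von
    Karman refractive-index fields, phase projection, 12-bit intensity
    rendering, and Gaussian feature cohorts) with known ground truth so
    the whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    class,
    dplyr,
    e1071,
    jsonlite,
    minpack.lm,
    nnet,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
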