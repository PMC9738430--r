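# pcparams

Phase-contrast microscopy parameters for label-free discrimination of
healthy and tumoral tissue.

Fresh, unstained tissue slices are nearly transparent; phase-contrast
microscopy makes them visible by converting optical path-length variation
(refractive index × thickness) into intensity contrast. `pcparams`
implements an analysis pipeline that reduces each phase-contrast image to
five physically interpretable parameters, screens those parameters for
healthy-versus-tumoral significance, and benchmarks eight standard
classifiers on the resulting feature tables. It is aimed at researchers in
quantitative phase imaging and digital histopathology who want a tested,
reproducible reference implementation of this parameter set — and a
synthetic phantom generator with known ground truth, so every stage can be
validated without access to clinical images.

## The five parameters

For a phase map φ(r) (radians) of a slice of thickness L imaged at
wavelength λ, with β₀ = 2π/λ:

| Parameter | Definition | Unit |
|---|---|---|
| Refractive index variance (RIV) | σₙ² = ⟨\|∇φ\|²⟩ / β₀² | — |
| Scattering coefficient (SC) | μₛ = ⟨Δφ²(r)⟩ / L | rad²/mm |
| Anisotropy factor (AF) | g = (1 − x)², x = ⟨\|∇φ\|²⟩ / (2k₀²⟨Δφ²⟩) | — |
| Outer scale (OS) | L₀ from the Von Kármán fit Φ(κ) = 4πσₙ²L₀²(m−1)(1+κ²L₀²)^−m | µm |
| Fractal dimension (FD) | d_f = 4 − m (spectral), or box counting | — |

The significance screen is a per-cell one-way ANOVA (Snedecor F, operative
rule p < 0.005). The classifier bench covers LDA, QDA, Gaussian and kernel
naive Bayes, kNN (k = 5), a linear SVM, a decision tree (minimum parent
size 10) and a 10-unit single-hidden-layer neural network, evaluated by
re-substitution and repeated stratified cross-validation, with errors
decomposed into false-positive and false-negative rates (total = FP + FN,
tumoral = positive class).

See `vignettes/phase-contrast-discrimination.Rmd` for the methods account:
model assumptions, estimator conventions, phantom design, and limitations.

## Worked example

Extract the five parameters from a synthetic phantom with known ground
truth (field variance 0.01, outer scale 8 µm, exponent 1.5):

```r
library(pcparams)

ph <- field_to_phase(generate_von_karman_field(
  field_spec(c(256, 256), 0.3225, sigma_n2 = 0.01, outer_scale = 8,
             exponent = 1.5, seed = 11)), thickness = 6, wavelength = 0.55)
extract_features(ph, acquisition_config("20x"))
#> # A tibble: 1 x 11
#>     riv sc_rad2_per_mm    af    fd os_um     m sigma_n2_fit converged
#>   <dbl>          <dbl> <dbl> <dbl> <dbl> <dbl>        <dbl> <lgl>
#> 1 0.240          6069. 0.993  2.53  6.07  1.47      0.00731 TRUE
```

The fitted outer scale (6.07 µm) and exponent (1.47) recover the generator's
ground truth (8 µm, 1.5) to within the sampling error of a single 256²
realization; the fractal dimension 2.53 is exactly 4 − m; the anisotropy
0.993 reflects strongly forward scattering.

Worked mean-difference screening from the bundled reference group
statistics (ganglion scattering coefficient at 20×):

```r
s <- reference_group_stats()
h <- subset(s, tissue == "ganglion" & magnification == "20x" &
               parameter == "sc" & state == "healthy")
t <- subset(s, tissue == "ganglion" & magnification == "20x" &
               parameter == "sc" & state == "tumoral")
mean_difference(h, t)
#> # A tibble: 1 x 9
#>   tissue   magnification parameter mean_healthy mean_tumoral abs_diff ...
#> 1 ganglion 20x           sc                43.5         18.1     25.4
```

The difference (25.39 rad²/mm) exceeds both group SDs (12.91, 15.31) —
`exceeds = "both"` — marking this parameter/magnification as a promising
discriminator, which the classifier bench confirms:

```r
cohort <- generate_feature_cohort(
  reference_cohort_spec("ganglion", "20x", n_per_group = 100, seed = 1))
cross_validation_errors(classifier_spec("LDA", seed = 1), cohort,
                        features = "sc")
#> # A tibble: 1 x 5
#>   fp_rate fn_rate total sensitivity specificity
#> 1   0.128   0.178 0.306       0.822       0.872
```

A full simulate → extract → stats → classify run, with provenance headers
on every output file:

```r
run_pipeline(run_config("my_run", seed = 1))
```

or from the shell via the thin wrapper `inst/cli/pcparams.R`.

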