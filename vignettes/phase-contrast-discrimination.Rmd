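---
title: "Phase-contrast parameters for label-free tissue discrimination: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-contrast parameters for label-free tissue discrimination: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcparams)
```

## The problem

Fresh, unstained (label-free) tissue slices are nearly transparent, so
phase-contrast microscopy is the natural way to image them: it converts
optical path-length variation — refractive index times thickness — into
intensity contrast. The question this package addresses is whether a small
set of physically interpretable parameters computed from such images can
discriminate healthy from tumoral tissue automatically, without fixation or
staining, and how well standard classifiers do on those parameters.

`pcparams` implements the full analysis chain: a synthetic phantom generator
with known ground truth, per-image estimation of five phase-contrast
parameters, a one-way ANOVA significance screen, and an eight-classifier
benchmark whose errors are decomposed into false-positive and false-negative
rates.

## The five parameters

All five derive from the phase map $\varphi(r)$ (radians) of a thin slice of
thickness $L$ imaged at wavelength $\lambda$, with $\beta_0 = 2\pi/\lambda$
the vacuum wavenumber.

**Refractive index variance (RIV).** For a weakly scattering slice the
spatial variance of the refractive index is estimated from the mean squared
phase gradient:
$$\sigma_n^2 = \frac{\langle |\nabla\varphi|^2 \rangle}{\beta_0^2}.$$
Gradients are central differences scaled by the pixel size, one-sided at the
borders, with no apodization.

**Scattering coefficient (SC).** The scattering-phase relation links the
phase spatial variance to the scattering coefficient:
$$\mu_s = \frac{\langle \Delta\varphi^2(r) \rangle}{L},$$
reported in rad²/mm. $\Delta\varphi$ is the deviation from the spatial mean;
the variance uses divisor $N$ (population convention).

**Anisotropy factor (AF).** With
$x = \langle|\nabla\varphi|^2\rangle \,/\, (2 k_0^2 \langle\Delta\varphi^2\rangle)$,
$$g = (1 - x)^2 .$$
Slowly varying phase drives $x \to 0$ and $g \to 1$, the strongly
forward-scattering regime typical of soft tissue. Because the printed form
of this estimator is typographically ambiguous in parts of the literature
(square of the bracket versus no square), both forms are implemented
(`form = "outer_square"`, the default, and `"no_square"`), and the form used
is recorded with every extraction. Likewise the incident wavenumber $k_0$
defaults to the vacuum convention $k_0 = \beta_0$, with a `"medium"` option
($k_0 = n_0\beta_0$) selectable in `acquisition_config()`.

**Outer scale (OS) and spectral exponent.** The spatial spectrum of
refractive-index heterogeneity in tissue is well approximated by a
Von Kármán form borrowed from turbulence theory,
$$\Phi(\kappa) = 4\pi\,\sigma_n^2 L_0^2 (m - 1)\,(1 + \kappa^2 L_0^2)^{-m},$$
where $L_0$ (µm) is the outer scale — the largest correlation length of the
heterogeneity — and $m$ the spectral exponent. With the convention
$\mathrm{Var} = \int \Phi\, d^2\kappa/(2\pi)^2$ this spectrum integrates
exactly to $\sigma_n^2$. The package estimates $(\sigma_n^2, L_0, m)$ by
Levenberg–Marquardt least squares on the log of the radially averaged
periodogram.

**Fractal dimension (FD).** From the spectral exponent via the identity
$d_f = 4 - m$ (exact for every converged fit), or independently by
box-counting on an Otsu-binarized phase map (slope of log occupied boxes
against log inverse box size, dyadic sizes 2 … min(H, W)/4). Box-counting is
one of several valid counting estimators; Otsu thresholding is likewise one
defensible binarization choice among several.

## Spectrum estimation choices

The radial spectrum uses angular spatial frequency $\kappa$ (rad/µm),
logarithmic radial bins (40 by default, minimum 32), excludes the DC bin,
and caps the band at 0.8× the angular Nyquist frequency to avoid spectral
leakage and the flat noise floor near Nyquist. Phase images are converted to
index fluctuation via $n - n_0 = \varphi/(\beta_0 L)$ before the transform.

The Von Kármán fit starts from $L_0 =$ extent/4, $m = 3$, and a plug-in
variance, with bounds $m \in (1.01, 6]$ and $L_0 \in$ (pixel, 10× extent).
A fit that lands on a bound — as happens for white noise, which has no outer
scale — is reported with `converged = FALSE` rather than an error;
downstream consumers (e.g. `extract_features()`) translate that flag into
missing values for $L_0$ and $d_f$. Degenerate images (zero variance) yield
flagged missing values rather than exceptions, so batch runs always
complete.

Intensity-to-phase conversion assumes the weak-phase linear camera model
$\text{counts} = \text{offset} + \text{gain}\cdot\varphi$; absolute
parameter values need the (gain, offset) calibration, and a `"relative"`
mode normalizes counts to [0, 1] and flags every downstream value as
scale-relative. Classification is unaffected by a global scale per cohort.

## The phantom generator

Because no public image set accompanies the study design this package
emulates, all testing rests on synthetic phantoms with known ground truth:

* **Fields.** Zero-mean Gaussian random fields with the Von Kármán spectrum,
  synthesized by frequency-domain filtering of white noise (periodic
  boundaries, DC bin zeroed). The filter is normalized by the *discrete*
  spectral sum so the field's expected sample variance equals the requested
  $\sigma_n^2$ exactly, regardless of how the finite grid truncates the
  continuous spectral integral. The spectrum is taken as isotropic,
  $\Phi(|\kappa|)$.
* **Phase and camera.** Fields are projected to phase by
  $(2\pi/\lambda)\, n\, L$ and rendered to quantized counts with gain,
  offset, clipping at $2^{12}-1$, and Gaussian read noise; saturation above
  1% warns. These scalings are exact by construction, which the tests
  exploit.
* **Feature cohorts.** Labeled feature tables are drawn as independent
  Gaussians per parameter, parameterized by the bundled
  `reference_group_stats()` table of per-group means and SDs for five tissue
  types at three magnifications, or by any user-supplied `cohort_spec()`.

What the phantoms deliberately do *not* emulate: tissue morphology (nuclei,
vessels), the halo and shade-off artifacts of phase-contrast optics, mosaic
stitching, or cross-parameter covariance in the cohorts (no covariance
information is available in the reference statistics). Passing tests
therefore demonstrate that the estimators and the benchmark machinery are
correct, not that real tissue follows the model.

## Default acquisition

Pixel sizes default to 0.64, 0.3225 and 0.1632 µm for 10×, 20× and 40×
objectives, the slice thickness to 6 µm (fresh cryo-sections). The
illumination wavelength (0.55 µm) and the mean tissue index $n_0 = 1.35$
are conventional mid-visible / soft-tissue values, configurable in
`acquisition_config()`; reports record the conventions used.

## The significance screen

For every (parameter, magnification, tissue) cell a one-way ANOVA compares
the healthy and tumoral groups; the operative significance rule is
$p < 0.005$. Summaries use the sample SD (divisor $n-1$); the ANOVA uses
the standard sums-of-squares decomposition (for two groups $F$ equals the
squared pooled two-sample $t$, which the tests assert to $10^{-10}$). No
multiple-testing correction is applied — the screen is descriptive, and the
report records the number of tests performed. Worked mean-difference
reports round to each parameter's conventional reporting precision (RIV 4
decimals, SC 2, AF 5, FD 3, OS 2). Images are treated as independent
experimental units.

## The classifier bench

Eight classifiers, all operating on features z-scored with training-split
statistics only (leak-free): LDA and QDA (empirical priors), Gaussian naive
Bayes, kernel naive Bayes (Gaussian kernel densities, normal-reference
bandwidth per feature per class — implemented in-package), kNN (k = 5,
Euclidean), a linear-kernel SVM (a single binary machine: one-versus-one
coding is vacuous for two classes), a decision tree (Gini, binary splits,
minimum parent size 10, no cost-complexity pruning), and a single-hidden-
layer neural network of 10 units with cross-entropy loss (up to 500
iterations; the quasi-Newton optimizer of `nnet` rather than scaled
conjugate gradients — the loss and architecture, not the optimizer, define
the model here). The wording "10 hidden layers" in parts of the applied
literature conventionally denotes one layer of 10 units; only that reading
is implemented.

Two error protocols, with tumoral as the positive class throughout:

* **Re-substitution**: train on all data, predict the same data. Optimistic
  by construction.
* **Cross-validation**: stratified 10-fold, repeated 5× with reshuffled
  folds (both configurable); held-out predictions are pooled per repeat and
  the FP/FN rates averaged over repeats. The seed fixes fold assignment, so
  reruns are identical.

The **total error is FP + FN** (the summed convention), so chance-level
two-class performance totals ≈ 1.0, not 0.5. Sensitivity $= 1 -$ FN and
specificity $= 1 -$ FP hold exactly for every report cell, and report cells
with total error < 0.1 are flagged. Constant feature columns are dropped at
standardization with a warning so covariance-based learners degrade
gracefully; rows with missing features are dropped with a warning.

## A worked example

```{r example, eval = FALSE}
# simulate a two-class feature cohort from the bundled reference statistics
spec <- reference_cohort_spec("ganglion", "20x", n_per_group = 100, seed = 1)
cohort <- generate_feature_cohort(spec)

# significance screen
significance_table(cohort)

# single-feature LDA benchmark on the scattering coefficient
cross_validation_errors(classifier_spec("LDA", seed = 1), cohort,
                        features = "sc")
```

The ganglion scattering coefficient at 20× has a standardized mean
separation of ≈ 1.8 SD, versus ≈ 0.25 at 10×; the cross-validated
single-feature LDA error reproduces that ordering, which is one of the
package's end-to-end checks.

## Numerical and design notes

* Seeds: every stochastic stage takes an explicit integer seed; the
  pipeline's single global seed fans out to stage seeds by a fixed integer
  derivation, so identical configurations reproduce outputs byte-for-byte.
* Test problem sizes: estimator-versus-oracle checks run on 64² images,
  where brute-force loop oracles are exact and fast; spectrum-recovery
  checks use a single 1024² field; the type-I-error simulation uses 2000
  null replicates; the classifier bench uses 100 observations per class.
  These sizes make each property statistically decisive while keeping the
  whole suite in the tens of seconds.
* Degenerate inputs (constant images, zero SDs, single-class cells, cells
  missing one state) produce flagged missing values or structured warnings,
  never silent wrong numbers and never hard failures mid-batch.
* kNN vote ties cannot occur for two classes with odd k; distance ties are
  handled by including all equidistant neighbors.

## Limitations

* The reference statistics summarize group means and SDs only; simulated
  cohorts are independent Gaussians per parameter and cannot reproduce
  cross-parameter correlation, heavy tails, or per-patient clustering in
  real feature tables.
* Absolute parameter magnitudes from real phase-contrast images depend on
  the unknown count-to-radian calibration of the camera; only the relative
  (per-cohort) structure is calibration-free.
* Phase unwrapping is not implemented: thin fresh slices are assumed to stay
  in the weak-phase regime.
* The outer-scale estimate is only meaningful when $L_0$ is well inside the
  resolved frequency band; fields whose outer scale approaches the field of
  view return unconverged fits, by design.
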