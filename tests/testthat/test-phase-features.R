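acq20 <- acquisition_config("20x")

test_that("gradient, variance and anisotropy match closed forms on constructed images", {
  flat <- phase_image(matrix(1.5, 32, 32), 1)
  expect_equal(gradient_square_mean(flat), 0)
  expect_equal(phase_spatial_variance(flat), 0)

  # ramp phi = a x: gradient exactly a^2 everywhere (one-sided included)
  a <- 0.7
  r <- ramp_phase(64, a = a, px = 0.5)
  expect_equal(gradient_square_mean(r), a^2, tolerance = 1e-12)

  # riv closed form for a unit ramp: (lambda / 2 pi)^2
  r1 <- ramp_phase(64, a = 1, px = 0.5)
  expect_equal(refractive_index_variance(r1, acq20), (0.55 / (2 * pi))^2,
               tolerance = 1e-12)

  cb <- checkerboard_phase(32, c = 0.5)
  expect_equal(phase_spatial_variance(cb), 0.25, tolerance = 1e-12)

  expect_error(gradient_square_mean(matrix(0, 2, 2), pixel_size = 1),
               "3 x 3")
})

test_that("scattering coefficient follows the variance-over-thickness rule", {
  cb <- checkerboard_phase(32, c = sqrt(0.5))   # variance 0.5 rad^2
  acq <- acquisition_config("20x", thickness = 6)
  expect_equal(scattering_coefficient(cb, acq), 0.5 / 0.006,
               tolerance = 1e-12)
  half <- acquisition_config("20x", thickness = 3)
  expect_equal(scattering_coefficient(cb, half),
               2 * scattering_coefficient(cb, acq), tolerance = 1e-12)
})

test_that("estimators equal naive loop oracles on phantom images", {
  ph <- phantom_phase(64, seed = 21)
  g <- oracle_gradient_square_mean(ph$phi, ph$pixel_size)
  expect_equal(gradient_square_mean(ph), g, tolerance = 1e-12)
  v <- oracle_phase_variance(ph$phi)
  expect_equal(phase_spatial_variance(ph), v, tolerance = 1e-12)
  expect_equal(refractive_index_variance(ph, acq20),
               g / (2 * pi / 0.55)^2, tolerance = 1e-12)
  expect_equal(anisotropy_factor(ph, acq20),
               oracle_anisotropy(ph$phi, ph$pixel_size, 0.55),
               tolerance = 1e-12)
  expect_equal(anisotropy_factor(ph, acq20, form = "no_square"),
               oracle_anisotropy(ph$phi, ph$pixel_size, 0.55, FALSE),
               tolerance = 1e-12)
})

test_that("anisotropy limits behave as the formula dictates", {
  # slowly varying phase: g -> 1 (strongly forward scattering)
  slow <- phase_image(outer(1:64, 1:64,
                            function(i, j) sin(i / 40) + cos(j / 35)),
                      pixel_size = 0.3225)
  expect_gt(anisotropy_factor(slow, acq20), 0.99)

  # choose the wavelength so that x = 1: g = 0 in both forms
  ph <- phantom_phase(64, seed = 4)
  gsm <- gradient_square_mean(ph)
  pv <- phase_spatial_variance(ph)
  lam <- 2 * pi / sqrt(gsm / (2 * pv))
  acq_x1 <- acquisition_config("20x", wavelength = lam,
                               pixel_size = ph$pixel_size)
  expect_equal(anisotropy_factor(ph, acq_x1), 0, tolerance = 1e-12)
  expect_equal(anisotropy_factor(ph, acq_x1, form = "no_square"), 0,
               tolerance = 1e-12)

  # zero variance: flagged missing, not an exception
  flat <- phase_image(matrix(2, 32, 32), 1)
  expect_warning(g0 <- anisotropy_factor(flat, acq20), "undefined")
  expect_true(is.na(g0))
})

test_that("medium wavenumber convention rescales the anisotropy argument by n0^2", {
  ph <- phantom_phase(64, seed = 6)
  vac <- acquisition_config("20x", k0_convention = "vacuum")
  med <- acquisition_config("20x", k0_convention = "medium")
  x_vac <- 1 - sqrt(anisotropy_factor(ph, vac))
  x_med <- 1 - sqrt(anisotropy_factor(ph, med))
  expect_equal(x_vac / x_med, 1.35^2, tolerance = 1e-10)
})

test_that("adding a constant phase offset changes no parameter", {
  ph <- phantom_phase(64, seed = 9)
  shifted <- phase_image(ph$phi + 3.2, ph$pixel_size)
  expect_equal(refractive_index_variance(shifted, acq20),
               refractive_index_variance(ph, acq20), tolerance = 1e-12)
  expect_equal(scattering_coefficient(shifted, acq20),
               scattering_coefficient(ph, acq20), tolerance = 1e-12)
  expect_equal(anisotropy_factor(shifted, acq20),
               anisotropy_factor(ph, acq20), tolerance = 1e-12)
  f1 <- fit_von_karman(radial_power_spectrum(ph, acq20))
  f2 <- fit_von_karman(radial_power_spectrum(shifted, acq20))
  expect_equal(f2$outer_scale, f1$outer_scale, tolerance = 1e-8)
  expect_equal(f2$exponent, f1$exponent, tolerance = 1e-8)
})

test_that("calibrated phase recovery inverts the camera model", {
  ph <- phantom_phase(64, seed = 13)
  img <- render_intensity_image(ph, gain = 50, offset = 2000, noise_sd = 0)
  rec <- intensity_to_phase(img)
  expect_lt(max(abs(rec$phi - ph$phi)), 0.5 / 50)

  # offset-only image: zero phase everywhere
  off <- structure(list(counts = matrix(700, 32, 32), bit_depth = 12L,
                        gain = 350, offset = 700, pixel_size = 1),
                   class = "intensity_image")
  expect_true(all(intensity_to_phase(off)$phi == 0))

  # halving the assumed gain doubles phase, quadrupling sigma_n2
  r1 <- refractive_index_variance(intensity_to_phase(img, gain = 50), acq20)
  r2 <- refractive_index_variance(intensity_to_phase(img, gain = 100), acq20)
  expect_equal(r1 / r2, 4, tolerance = 1e-10)

  # relative mode flags its output; missing calibration is instructive
  rel <- intensity_to_phase(img, mode = "relative")
  expect_true(rel$provenance$relative_phase)
  expect_error(intensity_to_phase(matrix(1:400, 20, 20), pixel_size = 1),
               "relative")
})

test_that("radial spectrum is flat for white noise and peaked for a sinusoid", {
  wn <- withr::with_seed(5, matrix(rnorm(128^2), 128, 128))
  sp <- radial_power_spectrum(wn, pixel_size = 1)
  slope <- unname(coef(lm(log(sp$density) ~ log(sp$kappa)))[2])
  expect_lt(abs(slope), 0.08)

  kstar <- 2 * pi * 16 / 128    # 16 cycles across a 128-pixel field
  sine <- outer(1:128, 1:128, function(i, j) sin(kstar * i))
  sps <- radial_power_spectrum(sine, pixel_size = 1)
  expect_lt(abs(sps$kappa[which.max(sps$density)] - kstar) / kstar, 0.1)

  expect_error(radial_power_spectrum(matrix(0, 32, 32), pixel_size = 1),
               "64 x 64")
})

test_that("radial spectrum equals the DFT-matrix oracle on 64x64 input", {
  f <- generate_von_karman_field(
    field_spec(c(64, 64), 0.3225, 0.01, 10, 1.4, seed = 2))
  sp <- radial_power_spectrum(f)
  or <- oracle_radial_spectrum(f$values, 0.3225)
  expect_equal(sp$kappa, or$kappa, tolerance = 1e-10)
  expect_equal(sp$density, or$density, tolerance = 1e-10)
})

test_that("Von Karman fit recovers exact analytic samples to 1e-3", {
  kappa <- exp(seq(log(0.05), log(5), length.out = 40))
  sp <- tibble::tibble(kappa = kappa,
                       density = von_karman_spectrum(kappa, 0.01, 40, 1.3))
  fit <- fit_von_karman(sp)
  expect_true(fit$converged)
  expect_lt(abs(fit$outer_scale - 40) / 40, 1e-3)
  expect_lt(abs(fit$exponent - 1.3) / 1.3, 1e-3)
  expect_lt(abs(fit$sigma_n2_fit - 0.01) / 0.01, 1e-3)
  expect_lt(fit$residual_rms, 1e-6)
})

test_that("white-noise spectra do not masquerade as converged Von Karman fits", {
  wn <- withr::with_seed(8, matrix(rnorm(128^2), 128, 128))
  fit <- fit_von_karman(radial_power_spectrum(wn, pixel_size = 0.3225))
  expect_false(fit$converged)
})

test_that("fractal dimension identities and box counting hold", {
  mk_fit <- function(m, conv = TRUE)
    structure(list(exponent = m, converged = conv), class = "spectrum_fit")
  expect_equal(fractal_dimension(mk_fit(1.3)), 2.7)
  expect_equal(fractal_dimension(mk_fit(1.0)), 3.0)
  expect_warning(fd <- fractal_dimension(mk_fit(1.3, conv = FALSE)),
                 "unconverged")
  expect_true(is.na(fd))

  # spectral identity df + m = 4 for every converged phantom fit
  for (seed in 1:3) {
    ph <- phantom_phase(128, seed = seed)
    fit <- fit_von_karman(radial_power_spectrum(ph, acq20))
    if (fit$converged)
      expect_equal(fractal_dimension(fit) + fit$exponent, 4)
  }

  # depth-5 Sierpinski carpet: dimension log 8 / log 3 within 0.05
  d <- fractal_dimension(sierpinski_mask(5), method = "box_counting")
  expect_lt(abs(d - log(8) / log(3)), 0.05)
})

test_that("riv estimate increases monotonically with the prescribed field variance", {
  levels <- c(0.005, 0.01, 0.02, 0.04, 0.08)
  riv <- vapply(levels, function(s2) {
    ph <- phantom_phase(64, sigma_n2 = s2, seed = 31)  # paired seeds
    refractive_index_variance(ph, acq20)
  }, numeric(1))
  expect_equal(cor(riv, levels, method = "spearman"), 1)
})

test_that("extract_features composes the individual estimators and survives degenerate input", {
  ph <- phantom_phase(128, seed = 17)
  rec <- extract_features(ph, acq20)
  expect_equal(rec$riv, refractive_index_variance(ph, acq20))
  expect_equal(rec$sc_rad2_per_mm, scattering_coefficient(ph, acq20))
  expect_equal(rec$af, anisotropy_factor(ph, acq20))
  expect_true(rec$converged)
  expect_equal(rec$fd, 4 - rec$m)

  flat <- phase_image(matrix(1, 64, 64), 0.3225)
  rec0 <- extract_features(flat, acq20)
  expect_equal(rec0$riv, 0)
  expect_equal(rec0$sc_rad2_per_mm, 0)
  expect_true(is.na(rec0$af))
  expect_true(is.na(rec0$fd))
  expect_false(rec0$converged)
  expect_match(rec0$warnings, "undefined")
})
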