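test_that("field_spec rejects non-normalizable or invalid parameters", {
  expect_error(field_spec(c(32, 32), 0.64, 0.01, 80, exponent = 1),
               "exponent")
  expect_error(field_spec(c(32, 32), 0.64, 0.01, -5, 1.3), "outer_scale")
  expect_error(field_spec(c(32, 32), 0.64, -0.1, 80, 1.3), "sigma_n2")
  expect_error(field_spec(c(8, 8), 0.64, 0.01, 80, 1.3))
  expect_error(field_spec(c(32, 32), 0.64, Inf, 80, 1.3), "finite")
})

test_that("zero-amplitude spec yields the constant zero field", {
  f <- generate_von_karman_field(
    field_spec(c(64, 64), 0.64, sigma_n2 = 0, outer_scale = 80,
               exponent = 1.3, seed = 1))
  expect_true(all(f$values == 0))
  expect_equal(phase_spatial_variance(f$values), 0)
})

test_that("generated field is zero-mean, seeded-reproducible, and hits the target variance", {
  spec <- field_spec(c(1024, 1024), 0.3225, sigma_n2 = 0.02,
                     outer_scale = 40, exponent = 1.3, seed = 7)
  f1 <- generate_von_karman_field(spec)
  f2 <- generate_von_karman_field(spec)
  expect_identical(f1$values, f2$values)        # bit-identical per seed
  expect_lt(abs(mean(f1$values)), 1e-12)
  # sample variance fluctuates around the target because the outer scale is
  # an appreciable fraction of the field extent (few independent patches)
  expect_lt(abs(phase_spatial_variance(f1$values) - 0.02) / 0.02, 0.15)
})

test_that("field variance scales linearly with sigma_n2 under paired seeds", {
  mk <- function(s2) generate_von_karman_field(
    field_spec(c(128, 128), 0.3225, s2, 10, 1.4, seed = 3))$values
  v1 <- phase_spatial_variance(mk(0.01))
  v2 <- phase_spatial_variance(mk(0.02))
  # same white-noise draw, amplitude scales as sqrt(sigma_n2): exact doubling
  expect_equal(v2 / v1, 2, tolerance = 1e-10)
})

test_that("spectral tail slope of a synthesized field follows the prescribed exponent", {
  f <- generate_von_karman_field(
    field_spec(c(1024, 1024), 0.3225, 0.01, outer_scale = 20,
               exponent = 1.5, seed = 11))
  sp <- radial_power_spectrum(f)
  sel <- sp$kappa * 20 >= 10 & sp$kappa * 20 <= 50
  slope <- unname(coef(lm(log(sp$density[sel]) ~ log(sp$kappa[sel])))[2])
  expect_lt(abs(slope - (-2 * 1.5)) / 3, 0.10)
})

test_that("realized radial spectrum matches the analytic Von Karman shape", {
  f <- generate_von_karman_field(
    field_spec(c(512, 512), 0.3225, 0.02, outer_scale = 15,
               exponent = 1.4, seed = 5))
  sp <- radial_power_spectrum(f)
  ratio <- sp$density / von_karman_spectrum(sp$kappa, 0.02, 15, 1.4)
  # log-ratio flat within periodogram noise across the resolved band
  expect_lt(abs(mean(log(ratio[-(1:3)]))), 0.25)
  expect_lt(abs(unname(coef(lm(log(ratio) ~ log(sp$kappa)))[2])), 0.1)
})

test_that("phase projection applies (2 pi / lambda) * n * L with exact scalings", {
  f <- generate_von_karman_field(
    field_spec(c(64, 64), 0.3225, 0.02, 40, 1.3, seed = 7))
  v <- phase_spatial_variance(f$values)
  ph <- field_to_phase(f, thickness = 6, wavelength = 0.55)
  expect_equal(phase_spatial_variance(ph$phi), (2 * pi / 0.55)^2 * v * 36,
               tolerance = 1e-12)
  # naive per-pixel recomputation
  expect_equal(ph$phi, 2 * pi / 0.55 * f$values * 6, tolerance = 1e-10)
  # thickness^2 and wavelength^-2 scalings are exact
  ph2 <- field_to_phase(f, thickness = 3, wavelength = 0.55)
  expect_equal(phase_spatial_variance(ph$phi) /
                 phase_spatial_variance(ph2$phi), 4, tolerance = 1e-10)
  ph3 <- field_to_phase(f, thickness = 6, wavelength = 1.10)
  expect_equal(phase_spatial_variance(ph$phi) /
                 phase_spatial_variance(ph3$phi), 4, tolerance = 1e-10)
  expect_error(field_to_phase(f, -1, 0.55), "thickness")
  expect_error(field_to_phase(f, 6, 0), "wavelength")
})

test_that("intensity rendering quantizes, clips, and round-trips", {
  zero <- phase_image(matrix(0, 32, 32), 1)
  img <- render_intensity_image(zero, gain = 300, offset = 2048,
                                noise_sd = 0)
  expect_true(all(img$counts == 2048))

  ramp <- ramp_phase(32, a = 0.1)
  img <- render_intensity_image(ramp, gain = 500, offset = 1000,
                                noise_sd = 0)
  rec <- intensity_to_phase(img)
  expect_lt(max(abs(rec$phi - ramp$phi)), 0.5 / 500)

  # noise SD is realized within 10%
  img_n <- render_intensity_image(zero, gain = 300, offset = 2048,
                                  noise_sd = 5, seed = 9)
  expect_lt(abs(sd(img_n$counts - 2048) - 5) / 5, 0.10)

  # heavy saturation warns
  big <- phase_image(matrix(100, 32, 32), 1)
  expect_warning(render_intensity_image(big, gain = 300, offset = 2048),
                 "saturated")
})

test_that("feature cohorts reproduce the specified group statistics", {
  spec <- reference_cohort_spec("ganglion", "20x", n_per_group = 200,
                                seed = 1)
  cohort <- generate_feature_cohort(spec)
  expect_equal(nrow(cohort), 400)
  for (st in c("healthy", "tumoral")) {
    g <- spec$groups[spec$groups$state == st, ]
    got <- mean(cohort$sc[cohort$state == st])
    se <- g$sc_sd / sqrt(200)
    expect_lt(abs(got - g$sc_mean), 3 * se)
  }
  # zero SD yields constant draws
  grp <- spec$groups[1, ]
  grp[paste0(c("riv", "sc", "af", "fd", "os"), "_sd")] <- 0
  const <- generate_feature_cohort(cohort_spec(grp, 10, seed = 2))
  expect_true(all(const$sc == grp$sc_mean))
  # large-n sample SD within 5%
  big <- generate_feature_cohort(cohort_spec(spec$groups[1, ], 1e4, seed = 5))
  expect_lt(abs(sd(big$sc) - spec$groups$sc_sd[1]) / spec$groups$sc_sd[1],
            0.05)
  expect_error(cohort_spec(transform(grp, sc_sd = -1), 10), "deviations")
})

test_that("fixture sets are written with a consistent manifest and round-trip", {
  dir <- withr::local_tempdir()
  plan <- tibble::tibble(
    tissue = c("alpha", "alpha"), state = c("healthy", "tumoral"),
    magnification = c("20x", "20x"), sigma_n2 = c(0.01, 0.016),
    outer_scale = c(30, 18), exponent = c(1.45, 1.25), shape = 64L,
    seed = c(101L, 102L))
  acq <- acquisition_config("20x")
  manifest <- write_fixture_set(plan, acq, dir, noise_sd = 0)
  expect_equal(nrow(manifest), 2)
  expect_true(all(file.exists(file.path(dir, manifest$path))))
  back <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(back$tissue, plan$tissue)
  expect_equal(back$pixel_size_um, rep(0.3225, 2))
  # refuses to clobber unless told to
  expect_error(write_fixture_set(plan, acq, dir), "overwrite")
  expect_silent(write_fixture_set(plan, acq, dir, noise_sd = 0,
                                  overwrite = TRUE))
  # counts survive the 16-bit container exactly
  img <- read_fixture_image(file.path(dir, manifest$path[1]), 0.3225,
                            manifest$gain[1], manifest$offset[1])
  expect_true(all(img$counts == round(img$counts)))
  expect_true(all(img$counts >= 0 & img$counts <= 4095))
})
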