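# Programmatic fixtures shared across test files.

ramp_phase <- function(n = 32, a = 1, px = 1) {
  # phi = a * x (rad), x in um along rows
  phase_image(matrix(rep(a * (0:(n - 1)) * px, each = n), n, n, byrow = FALSE),
              pixel_size = px)
}

checkerboard_phase <- function(n = 32, c = 0.5, px = 1) {
  m <- outer(1:n, 1:n, function(i, j) ifelse((i + j) %% 2 == 0, c, -c))
  phase_image(m, pixel_size = px)
}

phantom_phase <- function(n = 64, sigma_n2 = 0.01, outer_scale = 5,
                          exponent = 1.5, seed = 1, px = 0.3225,
                          thickness = 6, wavelength = 0.55) {
  f <- generate_von_karman_field(
    field_spec(c(n, n), px, sigma_n2, outer_scale, exponent, seed))
  field_to_phase(f, thickness, wavelength)
}

sierpinski_mask <- function(depth = 5) {
  in_carpet <- function(i, j) {
    for (d in seq_len(depth)) {
      if (i %% 3 == 1 && j %% 3 == 1) return(FALSE)
      i <- i %/% 3; j <- j %/% 3
    }
    TRUE
  }
  n <- 3^depth
  outer(0:(n - 1), 0:(n - 1), Vectorize(in_carpet))
}

# 5-feature two-class Gaussian cohort with a given standardized separation
# (delta in SD units applied to every feature)
two_class_cohort <- function(n_per_class = 100, delta = 10, seed = 42,
                             tissue = "synthetic", magnification = "20x") {
  withr::with_seed(seed, {
    mk <- function(state, shift) {
      tibble::tibble(
        tissue = tissue, state = state, magnification = magnification,
        riv = rnorm(n_per_class, shift), sc = rnorm(n_per_class, shift),
        af = rnorm(n_per_class, shift), fd = rnorm(n_per_class, shift),
        os = rnorm(n_per_class, shift))
    }
    dplyr::bind_rows(mk("healthy", 0), mk("tumoral", delta))
  })
}

null_cohort <- function(n_per_class = 100, seed = 7, ...) {
  two_class_cohort(n_per_class = n_per_class, delta = 0, seed = seed, ...)
}
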