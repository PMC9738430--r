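#' Mean squared phase gradient
#'
#' Spatial mean of |grad phi|^2 = (dphi/dx)^2 + (dphi/dy)^2 in rad^2/um^2,
#' with central differences in the interior, one-sided differences at the
#' borders, and derivatives scaled by the pixel size. This is the quantity
#' the refractive-index variance and the anisotropy factor are built from.
#'
#' @param phase A [phase_image()] or a bare matrix (then `pixel_size` is
#'   required).
#' @param pixel_size Pixel size in um for a bare matrix.
#' @return Scalar, rad^2/um^2.
#' @export
gradient_square_mean <- function(phase, pixel_size = NULL) {
  if (inherits(phase, "phase_image")) {
    phi <- phase$phi; px <- phase$pixel_size
  } else {
    phi <- as.matrix(phase); px <- pixel_size
    if (is.null(px)) stop("pixel_size is required for a bare matrix")
  }
  if (nrow(phi) < 3L || ncol(phi) < 3L)
    stop("image must be at least 3 x 3 for gradient estimation")
  gx <- finite_diff_rows(phi) / px
  gy <- t(finite_diff_rows(t(phi))) / px
  mean(gx^2 + gy^2)
}

# d/d(row index): central differences inside, one-sided at the two borders
finite_diff_rows <- function(m) {
  n <- nrow(m)
  d <- m
  d[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / 2
  d[1, ] <- m[2, ] - m[1, ]
  d[n, ] <- m[n, ] - m[n - 1, ]
  d
}

#' Refractive index variance (RIV) from a phase image
#'
#' sigma_n^2 = <|grad phi|^2> / beta0^2 with beta0 = 2*pi/lambda: the mean
#' squared phase gradient rescaled by the vacuum wavenumber, giving a
#' dimensionless estimate of the spatial variance of the refractive index.
#'
#' @param phase A [phase_image()].
#' @param acq An [acquisition_config()].
#' @return Scalar sigma_n^2 (dimensionless).
#' @export
refractive_index_variance <- function(phase, acq) {
  stopifnot(inherits(acq, "acquisition_config"))
  gradient_square_mean(phase) / beta0(acq)^2
}

#' Spatial variance of the phase map
#'
#' Variance of phi about its spatial mean, population convention (divisor N).
#'
#' @param phase A [phase_image()] or matrix.
#' @return Scalar, rad^2.
#' @export
phase_spatial_variance <- function(phase) {
  phi <- if (inherits(phase, "phase_image")) phase$phi else as.matrix(phase)
  mean((phi - mean(phi))^2)
}

#' Scattering coefficient (SC) from a phase image
#'
#' The scattering-phase relation mu_s = <Delta phi^2(r)> / L: phase spatial
#' variance divided by slice thickness, reported in rad^2/mm.
#'
#' @param phase A [phase_image()].
#' @param acq An [acquisition_config()] (thickness in um).
#' @return Scalar mu_s in rad^2/mm.
#' @export
scattering_coefficient <- function(phase, acq) {
  stopifnot(inherits(acq, "acquisition_config"))
  if (acq$thickness <= 0) stop("thickness must be > 0")
  phase_spatial_variance(phase) / (acq$thickness / 1000)
}

#' Anisotropy factor (AF) from a phase image
#'
#' With x = <|grad phi|^2> / (2 k0^2 <Delta phi^2>), the anisotropy of
#' scattering is g = (1 - x)^2 (form `"outer_square"`, the default) or
#' g = 1 - x (form `"no_square"`). Slowly varying phase drives x to 0 and g
#' to 1, i.e. strongly forward scattering. Zero phase variance makes g
#' undefined: `NA` is returned with a warning.
#'
#' @param phase A [phase_image()].
#' @param acq An [acquisition_config()]; its `k0_convention` selects the
#'   vacuum or in-medium incident wavenumber.
#' @param form `"outer_square"` or `"no_square"`.
#' @return Scalar g (dimensionless), `NA` when undefined.
#' @export
anisotropy_factor <- function(phase, acq,
                              form = c("outer_square", "no_square")) {
  stopifnot(inherits(acq, "acquisition_config"))
  form <- match.arg(form)
  pv <- phase_spatial_variance(phase)
  if (pv == 0) {
    warning("zero phase variance: anisotropy factor undefined")
    return(NA_real_)
  }
  x <- gradient_square_mean(phase) / (2 * k0(acq)^2 * pv)
  if (form == "outer_square") (1 - x)^2 else 1 - x
}

#' Extract the five phase-contrast parameters from one image
#'
#' Runs the full per-image feature extraction: refractive index variance,
#' scattering coefficient, anisotropy factor, and -- via the radial power
#' spectrum and its Von Karman fit -- outer scale, spectral exponent and
#' fractal dimension. Any sub-estimator failure (e.g. a degenerate constant
#' image) is recorded as an `NA` with a warning string; a record is always
#' emitted so batch runs complete.
#'
#' @param image An `intensity_image`, [phase_image()], or bare counts matrix.
#' @param acq An [acquisition_config()].
#' @param calibration Optional `list(gain =, offset =)` for intensity input;
#'   `"relative"` selects normalized relative-phase mode.
#' @param af_form Anisotropy-factor form, see [anisotropy_factor()].
#' @param fd_method `"spectral"` (df = 4 - m from the Von Karman fit) or
#'   `"box_counting"`.
#' @return One-row tibble: `riv`, `sc_rad2_per_mm`, `af`, `fd`, `os_um`, `m`,
#'   `sigma_n2_fit`, `converged`, `af_form`, `fd_method`, `warnings`.
#' @export
extract_features <- function(image, acq, calibration = NULL,
                             af_form = c("outer_square", "no_square"),
                             fd_method = c("spectral", "box_counting")) {
  stopifnot(inherits(acq, "acquisition_config"))
  af_form <- match.arg(af_form)
  fd_method <- match.arg(fd_method)
  warnings <- character()
  note <- function(w) warnings <<- c(warnings, conditionMessage(w))

  phase <- if (inherits(image, "phase_image")) {
    image
  } else if (identical(calibration, "relative")) {
    intensity_to_phase(image, mode = "relative", pixel_size = acq$pixel_size)
  } else {
    intensity_to_phase(image, gain = calibration$gain,
                       offset = calibration$offset,
                       pixel_size = acq$pixel_size)
  }

  grab <- function(expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        warnings <<- c(warnings, conditionMessage(e)); NA_real_
      }),
      warning = function(w) { note(w); invokeRestart("muffleWarning") })
  }

  riv <- grab(refractive_index_variance(phase, acq))
  sc <- grab(scattering_coefficient(phase, acq))
  af <- grab(anisotropy_factor(phase, acq, form = af_form))

  fit <- withCallingHandlers(
    tryCatch(fit_von_karman(radial_power_spectrum(phase, acq)),
             error = function(e) {
               warnings <<- c(warnings, conditionMessage(e)); NULL
             }),
    warning = function(w) { note(w); invokeRestart("muffleWarning") })

  os <- if (!is.null(fit) && fit$converged) fit$outer_scale else NA_real_
  m <- if (!is.null(fit)) fit$exponent else NA_real_
  s2fit <- if (!is.null(fit)) fit$sigma_n2_fit else NA_real_
  conv <- if (!is.null(fit)) fit$converged else FALSE
  if (!conv) warnings <- c(warnings, "Von Karman fit did not converge")

  fd <- if (fd_method == "spectral") {
    if (conv) 4 - fit$exponent else NA_real_
  } else {
    grab(fractal_dimension(phase, method = "box_counting"))
  }

  tibble(riv = riv, sc_rad2_per_mm = sc, af = af, fd = fd, os_um = os,
         m = m, sigma_n2_fit = s2fit, converged = conv,
         af_form = af_form, fd_method = fd_method,
         warnings = paste(unique(warnings), collapse = "; "))
}

#' Extract features for every image in a manifest
#'
#' @param manifest Manifest tibble or path to a `manifest.csv` written by
#'   [write_fixture_set()].
#' @param dir Directory holding the images (defaults to the manifest's
#'   directory when a path is given).
#' @param ... Passed to [extract_features()].
#' @return A tibble with one row per image: manifest columns plus features.
#' @export
extract_features_batch <- function(manifest, dir = NULL, ...) {
  if (is.character(manifest)) {
    if (is.null(dir)) dir <- dirname(manifest)
    manifest <- as_tibble(read.csv(manifest, stringsAsFactors = FALSE,
                                   comment.char = "#"))
  }
  stopifnot(is.data.frame(manifest), !is.null(dir))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    acq <- acquisition_config(r$magnification, wavelength = r$wavelength_um,
                              thickness = r$thickness_um,
                              pixel_size = r$pixel_size_um)
    img <- read_fixture_image(file.path(dir, r$path), r$pixel_size_um,
                              r$gain, r$offset)
    dplyr::bind_cols(r, extract_features(img, acq, ...))
  })
  dplyr::bind_rows(rows)
}
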