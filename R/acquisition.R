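#' Optical and geometric acquisition context
#'
#' Bundles the quantities every phase-parameter estimator needs: illumination
#' wavelength, slice thickness, pixel size, objective magnification and the
#' sample's mean refractive index. Pixel size defaults to the
#' per-magnification values 0.64 / 0.3225 / 0.1632 um for 10x / 20x / 40x.
#' The wavenumber convention `k0_convention` selects whether the incident
#' wavevector used by the anisotropy factor is the vacuum wavenumber
#' beta0 = 2*pi/lambda (default) or the in-medium value n0 * beta0.
#'
#' @param magnification One of "10x", "20x", "40x".
#' @param wavelength Illumination wavelength in um (default 0.55, mid-visible;
#'   configurable because the camera's effective wavelength is setup
#'   dependent).
#' @param thickness Slice thickness L in um (default 6, fresh cryo-sections).
#' @param pixel_size Pixel size in um; `NULL` selects the per-magnification
#'   default.
#' @param mean_index Mean refractive index n0 (default 1.35, soft tissue).
#' @param k0_convention `"vacuum"` or `"medium"`.
#' @return An object of class `acquisition_config`.
#' @export
#' @examples
#' acquisition_config("20x")
acquisition_config <- function(magnification = c("10x", "20x", "40x"),
                               wavelength = 0.55, thickness = 6,
                               pixel_size = NULL, mean_index = 1.35,
                               k0_convention = c("vacuum", "medium")) {
  magnification <- match.arg(magnification)
  k0_convention <- match.arg(k0_convention)
  if (is.null(pixel_size)) pixel_size <- .default_pixel_size[[magnification]]
  stopifnot(wavelength > 0, thickness > 0, pixel_size > 0, mean_index > 0)
  structure(
    list(magnification = magnification, wavelength = wavelength,
         thickness = thickness, pixel_size = pixel_size,
         mean_index = mean_index, k0_convention = k0_convention),
    class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "<acquisition_config> %s, lambda %.3f um, L %.2f um, pixel %.4f um, n0 %.3f, k0 %s\n",
    x$magnification, x$wavelength, x$thickness, x$pixel_size, x$mean_index,
    x$k0_convention))
  invisible(x)
}

# pixel size for a manifest magnification label, honouring an override in acq
pixel_size_for <- function(acq, magnification) {
  if (acq$magnification == magnification) acq$pixel_size
  else .default_pixel_size[[magnification]]
}

# vacuum wavenumber beta0 = 2*pi/lambda (rad/um)
beta0 <- function(acq) 2 * pi / acq$wavelength

# incident wavenumber per the configured convention
k0 <- function(acq) {
  b <- beta0(acq)
  if (acq$k0_convention == "medium") acq$mean_index * b else b
}

#' Construct a phase image
#'
#' A 2-D map of optical phase phi(r) in radians with its pixel size.
#'
#' @param phi Numeric matrix of phase in radians, at least 16 x 16, finite.
#' @param pixel_size Pixel size in um (> 0).
#' @param provenance Optional list describing the image's origin (source
#'   path, phantom spec, calibration).
#' @return An object of class `phase_image`.
#' @export
phase_image <- function(phi, pixel_size, provenance = NULL) {
  phi <- as.matrix(phi)
  if (nrow(phi) < 16L || ncol(phi) < 16L)
    stop("phase image must be at least 16 x 16 pixels")
  if (!all(is.finite(phi))) stop("phase image must be finite")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(phi = phi, pixel_size = pixel_size, provenance = provenance),
            class = "phase_image")
}

#' @export
print.phase_image <- function(x, ...) {
  cat(sprintf("<phase_image> %d x %d px, pixel %.4f um, phase variance %.4g rad^2\n",
              nrow(x$phi), ncol(x$phi), x$pixel_size,
              mean((x$phi - mean(x$phi))^2)))
  invisible(x)
}

#' Convert camera counts to phase
#'
#' Inverts the weak-phase linear camera model: phi = (counts - offset) / gain.
#' When the calibration is unknown, `mode = "relative"` rescales counts to
#' \[0, 1\] and flags the result as relative phase: all downstream parameters
#' are then scale-relative (the refractive-index variance, for instance,
#' scales as gain^-2).
#'
#' @param image An `intensity_image`, or a plain counts matrix.
#' @param gain,offset Calibration in counts/rad and counts; taken from the
#'   `intensity_image` when omitted.
#' @param mode `"calibrated"` (default) or `"relative"`.
#' @param pixel_size Required when `image` is a bare matrix.
#' @return A [phase_image()]; in relative mode its provenance carries
#'   `relative_phase = TRUE`.
#' @export
intensity_to_phase <- function(image, gain = NULL, offset = NULL,
                               mode = c("calibrated", "relative"),
                               pixel_size = NULL) {
  mode <- match.arg(mode)
  if (inherits(image, "intensity_image")) {
    counts <- image$counts
    if (is.null(gain)) gain <- image$gain
    if (is.null(offset)) offset <- image$offset
    if (is.null(pixel_size)) pixel_size <- image$pixel_size
  } else {
    counts <- as.matrix(image)
    if (is.null(pixel_size)) stop("pixel_size is required for a bare matrix")
  }
  if (mode == "relative") {
    rng <- range(counts)
    phi <- if (diff(rng) == 0) counts * 0 else (counts - rng[1]) / diff(rng)
    return(phase_image(phi, pixel_size,
                       provenance = list(relative_phase = TRUE)))
  }
  if (is.null(gain) || is.null(offset)) {
    stop("calibrated mode needs gain (counts/rad) and offset (counts); ",
         "supply them or use mode = \"relative\"")
  }
  if (gain == 0) stop("gain must be nonzero")
  phase_image((counts - offset) / gain, pixel_size,
              provenance = list(relative_phase = FALSE, gain = gain,
                                offset = offset))
}
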