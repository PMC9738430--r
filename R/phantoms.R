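#' Specification of a synthetic refractive-index field
#'
#' Describes a two-dimensional zero-mean Gaussian random field of
#' refractive-index fluctuation n(r) - n0 whose isotropic power spectrum
#' follows the Von Karman form
#' \deqn{\Phi(\kappa) = 4\pi \sigma_n^2 L_0^2 (m - 1) (1 + \kappa^2 L_0^2)^{-m}}
#' with target spatial variance `sigma_n2`, outer scale `outer_scale` (um)
#' and spectral exponent `exponent` (m). The exponent must exceed 1 so the
#' prefactor (m - 1) is positive and the spectrum integrates to `sigma_n2`.
#'
#' @param shape Integer vector `c(H, W)` of pixels, both at least 16.
#' @param pixel_size Pixel size in um.
#' @param sigma_n2 Target spatial variance of the index fluctuation (>= 0).
#' @param outer_scale Outer scale L0 in um (> 0).
#' @param exponent Von Karman exponent m (> 1).
#' @param seed Integer seed; a fixed seed gives a bit-identical field.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(shape, pixel_size, sigma_n2, outer_scale, exponent,
                       seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- c(shape, shape)
  stopifnot(length(shape) == 2L, all(shape >= 16L))
  vals <- c(pixel_size, sigma_n2, outer_scale, exponent)
  if (!all(is.finite(vals))) stop("field_spec parameters must be finite")
  if (sigma_n2 < 0) stop("sigma_n2 must be >= 0")
  if (outer_scale <= 0) stop("outer_scale must be > 0")
  if (exponent <= 1) {
    stop("exponent must be > 1: the Von Karman prefactor (m - 1) must be positive")
  }
  structure(
    list(shape = shape, pixel_size = pixel_size, sigma_n2 = sigma_n2,
         outer_scale = outer_scale, exponent = exponent,
         seed = as.integer(seed)),
    class = "field_spec")
}

#' Analytic Von Karman spectral density
#'
#' Evaluates \eqn{\Phi(\kappa) = 4\pi \sigma_n^2 L_0^2 (m-1)(1+\kappa^2 L_0^2)^{-m}}
#' at angular spatial frequency `kappa` (rad/um). With the convention
#' \eqn{\mathrm{Var} = \int \Phi(\kappa)\, d^2\kappa / (2\pi)^2} the spectrum
#' integrates exactly to `sigma_n2`.
#'
#' @param kappa Angular spatial frequency, rad/um.
#' @param sigma_n2,outer_scale,exponent Spectrum parameters (see
#'   [field_spec()]).
#' @return Spectral density values, same length as `kappa`.
#' @export
von_karman_spectrum <- function(kappa, sigma_n2, outer_scale, exponent) {
  4 * pi * sigma_n2 * outer_scale^2 * (exponent - 1) *
    (1 + kappa^2 * outer_scale^2)^(-exponent)
}

# angular frequency grid (rad/um) along one FFT axis
fft_kappa <- function(n, pixel_size) {
  idx <- if (n %% 2 == 0) c(0:(n / 2), -(n / 2 - 1):-1)
         else c(0:((n - 1) / 2), -((n - 1) / 2):-1)
  2 * pi * idx / (n * pixel_size)
}

#' Generate a Von Karman refractive-index field
#'
#' Spectral synthesis: unit white Gaussian noise is filtered in the frequency
#' domain by the square root of the prescribed Von Karman spectrum (periodic
#' boundary conditions), the DC bin is zeroed (enforcing a zero-mean
#' fluctuation), and the filter amplitude is normalized by the discrete
#' spectral sum so the field's expected spatial variance equals
#' `spec$sigma_n2` regardless of grid truncation of the continuous integral.
#'
#' @param spec A [field_spec()].
#' @return An object of class `vk_field`: list with `values` (H x W matrix of
#'   index fluctuation n(r) - n0), `pixel_size` (um) and `spec`.
#' @export
#' @examples
#' f <- generate_von_karman_field(
#'   field_spec(c(64, 64), 0.3225, sigma_n2 = 0.01, outer_scale = 10,
#'              exponent = 1.5, seed = 1))
#' mean(f$values)   # ~ 0 by construction
generate_von_karman_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  h <- spec$shape[1]; w <- spec$shape[2]
  if (spec$sigma_n2 == 0) {
    values <- matrix(0, h, w)
  } else {
    kx <- fft_kappa(h, spec$pixel_size)
    ky <- fft_kappa(w, spec$pixel_size)
    kk <- sqrt(outer(kx^2, ky^2, `+`))
    amp <- sqrt(von_karman_spectrum(kk, spec$sigma_n2, spec$outer_scale,
                                    spec$exponent)) / spec$pixel_size
    amp[1, 1] <- 0
    # scale so the expected sample variance is exactly sigma_n2
    amp <- amp * sqrt(spec$sigma_n2 * (h * w) / sum(amp^2))
    values <- withr::with_seed(spec$seed, {
      noise <- matrix(rnorm(h * w), h, w)
      Re(fft(fft(noise) * amp, inverse = TRUE)) / (h * w)
    })
  }
  structure(list(values = values, pixel_size = spec$pixel_size, spec = spec),
            class = "vk_field")
}

#' @export
print.vk_field <- function(x, ...) {
  cat(sprintf(
    "<vk_field> %d x %d px, pixel %.4f um, sample variance %.4g\n",
    nrow(x$values), ncol(x$values), x$pixel_size, mean((x$values - mean(x$values))^2)))
  invisible(x)
}

#' Project a refractive-index field to a phase map
#'
#' For a thin, weakly scattering slice of thickness L the accumulated phase is
#' \eqn{\varphi(r) = (2\pi/\lambda)\,(n(r) - n_0)\,L} (radians). Phase
#' variance therefore scales exactly as thickness squared and wavelength to
#' the minus two.
#'
#' @param field A `vk_field` (or any list with `values` and `pixel_size`).
#' @param thickness Slice thickness L in um (> 0).
#' @param wavelength Illumination wavelength in um (> 0).
#' @return A [phase_image()].
#' @export
field_to_phase <- function(field, thickness, wavelength) {
  if (!is.list(field) || is.null(field$values) || is.null(field$pixel_size))
    stop("field must carry $values and $pixel_size")
  if (thickness <= 0) stop("thickness must be > 0")
  if (wavelength <= 0) stop("wavelength must be > 0")
  phase_image(2 * pi / wavelength * field$values * thickness,
              pixel_size = field$pixel_size,
              provenance = list(source = "phantom", spec = field$spec,
                                thickness = thickness, wavelength = wavelength))
}

#' Render a phase map as a quantized camera image
#'
#' Emulates a gray-scale CCD: counts = clip(round(offset + gain * phi +
#' Gaussian noise), 0, 2^bit_depth - 1). Gain and offset are recorded in the
#' returned object so [intensity_to_phase()] can invert the mapping. A
#' saturation fraction above 1% raises a warning.
#'
#' @param phase A [phase_image()].
#' @param bit_depth One of 8, 12 (default; typical scientific CCD) or 16.
#' @param gain Counts per radian (> 0).
#' @param offset Count offset.
#' @param noise_sd Read-noise SD in counts (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return An object of class `intensity_image`: `counts` matrix,
#'   `bit_depth`, `gain`, `offset`, `pixel_size`.
#' @export
render_intensity_image <- function(phase, bit_depth = 12L, gain, offset,
                                   noise_sd = 0, seed = 1L) {
  stopifnot(inherits(phase, "phase_image"))
  if (!bit_depth %in% c(8L, 12L, 16L)) stop("bit_depth must be 8, 12 or 16")
  if (gain <= 0) stop("gain must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  h <- nrow(phase$phi); w <- ncol(phase$phi)
  noise <- if (noise_sd > 0) {
    withr::with_seed(as.integer(seed), matrix(rnorm(h * w, 0, noise_sd), h, w))
  } else 0
  top <- 2^bit_depth - 1
  raw <- round(offset + gain * phase$phi + noise)
  counts <- pmin(pmax(raw, 0), top)
  sat <- mean(raw < 0 | raw > top)
  if (sat > 0.01) {
    warning(sprintf("%.1f%% of pixels saturated during rendering", 100 * sat))
  }
  structure(list(counts = counts, bit_depth = as.integer(bit_depth),
                 gain = gain, offset = offset, pixel_size = phase$pixel_size),
            class = "intensity_image")
}

#' Write a set of phantom images with an acquisition manifest
#'
#' Generates one Von Karman phantom per row of `plan`, projects it to phase,
#' renders a quantized intensity image and writes it as TIFF (16-bit
#' container), plus a `manifest.csv` describing every image.
#'
#' @param plan Data frame with columns `tissue`, `state` (healthy/tumoral),
#'   `magnification` (10x/20x/40x), `sigma_n2`, `outer_scale`, `exponent`,
#'   `seed`, and optionally `shape` (pixels per side, default 256).
#' @param acquisition An [acquisition_config()] providing wavelength,
#'   thickness and per-magnification pixel sizes.
#' @param output_dir Directory to write into (created if needed).
#' @param gain,offset,noise_sd Camera model passed to
#'   [render_intensity_image()].
#' @param overwrite Refuse to clobber an existing manifest unless TRUE.
#' @return The manifest as a tibble (also written to
#'   `file.path(output_dir, "manifest.csv")`) with columns `path`, `tissue`,
#'   `state`, `magnification`, `pixel_size_um`, `thickness_um`,
#'   `wavelength_um`, `seed`, `gain`, `offset`.
#' @export
write_fixture_set <- function(plan, acquisition, output_dir,
                              gain = 60, offset = 2048, noise_sd = 2,
                              overwrite = FALSE) {
  stopifnot(is.data.frame(plan), inherits(acquisition, "acquisition_config"))
  needed <- c("tissue", "state", "magnification", "sigma_n2", "outer_scale",
              "exponent", "seed")
  missing_cols <- setdiff(needed, names(plan))
  if (length(missing_cols))
    stop("plan is missing columns: ", paste(missing_cols, collapse = ", "))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(output_dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite)
    stop("manifest already exists at ", manifest_path,
         "; pass overwrite = TRUE to replace the fixture set")
  shape <- if ("shape" %in% names(plan)) plan$shape else rep(256L, nrow(plan))
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    px <- pixel_size_for(acquisition, plan$magnification[i])
    spec <- field_spec(shape[i], px, plan$sigma_n2[i], plan$outer_scale[i],
                       plan$exponent[i], seed = plan$seed[i])
    img <- render_intensity_image(
      field_to_phase(generate_von_karman_field(spec),
                     acquisition$thickness, acquisition$wavelength),
      bit_depth = 12L, gain = gain, offset = offset, noise_sd = noise_sd,
      seed = derive_seed(plan$seed[i], 17L))
    fname <- sprintf("phantom_%03d_%s_%s_%s.tiff", i, plan$tissue[i],
                     plan$state[i], plan$magnification[i])
    tiff::writeTIFF(img$counts / 65535, file.path(output_dir, fname),
                    bits.per.sample = 16L)
    tibble(path = fname, tissue = plan$tissue[i], state = plan$state[i],
           magnification = plan$magnification[i], pixel_size_um = px,
           thickness_um = acquisition$thickness,
           wavelength_um = acquisition$wavelength,
           seed = plan$seed[i], gain = gain, offset = offset)
  })
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  manifest
}

#' Read a fixture image written by [write_fixture_set()]
#'
#' @param path TIFF path (16-bit container holding 12-bit counts).
#' @param pixel_size Pixel size in um.
#' @param gain,offset Camera calibration recorded in the manifest.
#' @return An `intensity_image`.
#' @export
read_fixture_image <- function(path, pixel_size, gain, offset) {
  counts <- round(tiff::readTIFF(path) * 65535)
  structure(list(counts = counts, bit_depth = 12L, gain = gain,
                 offset = offset, pixel_size = pixel_size),
            class = "intensity_image")
}
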