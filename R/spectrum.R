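#' Radially averaged power spectrum of the refractive-index fluctuation
#'
#' Computes the 2-D periodogram of the zero-mean refractive-index fluctuation
#' and averages it azimuthally into logarithmic bins of angular spatial
#' frequency kappa (rad/um). A phase image is first converted to index
#' fluctuation via n - n0 = phi / (beta0 * L). The periodogram is calibrated
#' so that, with the convention Var = integral of Phi(kappa) d^2 kappa /
#' (2 pi)^2, its sum over frequency cells returns the sample variance
#' (Parseval). The DC bin is excluded and the band is capped at 0.8 x the
#' angular Nyquist frequency to avoid leakage and the noise floor.
#'
#' @param x A [phase_image()] (requires `acq`), a `vk_field`, or a bare
#'   matrix of index fluctuation (requires `pixel_size`).
#' @param acq An [acquisition_config()] (needed for phase input).
#' @param nbins Number of logarithmic radial bins (>= 32).
#' @param pixel_size Pixel size in um for a bare matrix.
#' @return A tibble with columns `kappa` (rad/um, bin-mean) and `density`
#'   (spectral density of the index fluctuation), with the usable band in
#'   attribute `kappa_band`.
#' @export
radial_power_spectrum <- function(x, acq = NULL, nbins = 40L,
                                  pixel_size = NULL) {
  if (nbins < 32L) stop("at least 32 radial bins are required")
  if (inherits(x, "phase_image")) {
    if (is.null(acq)) stop("acq is required to convert phase to index fluctuation")
    vals <- x$phi / (beta0(acq) * acq$thickness)
    px <- x$pixel_size
  } else if (inherits(x, "vk_field")) {
    vals <- x$values
    px <- x$pixel_size
  } else {
    vals <- as.matrix(x)
    px <- pixel_size
    if (is.null(px)) stop("pixel_size is required for a bare matrix")
  }
  h <- nrow(vals); w <- ncol(vals)
  if (h < 64L || w < 64L)
    stop("image must be at least 64 x 64 for meaningful radial bins")
  vals <- vals - mean(vals)
  pgram <- Mod(fft(vals))^2 * px^2 / (h * w)
  kk <- sqrt(outer(fft_kappa(h, px)^2, fft_kappa(w, px)^2, `+`))
  kappa_max <- 0.8 * pi / px
  kappa_min <- 2 * pi / (max(h, w) * px)
  sel <- kk > 0 & kk <= kappa_max
  breaks <- exp(seq(log(kappa_min * 0.999), log(kappa_max),
                    length.out = nbins + 1))
  bin <- cut(kk[sel], breaks, labels = FALSE)
  keep <- !is.na(bin)
  kbin <- tapply(kk[sel][keep], bin[keep], mean)
  pbin <- tapply(pgram[sel][keep], bin[keep], mean)
  out <- tibble(kappa = as.numeric(kbin), density = as.numeric(pbin))
  attr(out, "kappa_band") <- c(kappa_min, kappa_max)
  attr(out, "pixel_size") <- px
  attr(out, "extent_um") <- max(h, w) * px
  out
}

#' Fit the Von Karman spectrum model to a radial spectrum
#'
#' Nonlinear least squares of log density against log kappa for the model
#' \eqn{\Phi(\kappa) = 4\pi\,\sigma_n^2 L_0^2 (m-1)(1+\kappa^2 L_0^2)^{-m}},
#' estimating (sigma_n^2, L0, m) by Levenberg-Marquardt with bounds
#' m in (1.01, 6] and L0 in (pixel, 10 x field extent). Initial values:
#' L0 = extent / 4, m = 3, sigma_n^2 = the spectrum's integrated variance.
#' Non-convergence (including a fit pinned at a bound, as for white noise)
#' is reported via `converged = FALSE`; parameters are still returned and
#' downstream consumers must check the flag.
#'
#' @param spectrum Output of [radial_power_spectrum()] (>= 10 valid bins).
#' @param init Optional named list overriding initial values
#'   (`sigma_n2`, `outer_scale`, `exponent`).
#' @return An object of class `spectrum_fit`: `outer_scale` (um),
#'   `exponent` (m), `sigma_n2_fit`, `residual_rms` (log-scale RMS),
#'   `converged`, `kappa_band`.
#' @export
fit_von_karman <- function(spectrum, init = NULL) {
  ok <- is.finite(spectrum$kappa) & is.finite(spectrum$density) &
    spectrum$density > 0
  if (sum(ok) < 10L) stop("need at least 10 valid spectral bins to fit")
  df <- data.frame(kappa = spectrum$kappa[ok],
                   logd = log(spectrum$density[ok]))
  extent <- attr(spectrum, "extent_um")
  px <- attr(spectrum, "pixel_size")
  if (is.null(extent)) extent <- 2 * pi / min(df$kappa)
  if (is.null(px)) px <- pi / max(df$kappa)
  # plug-in variance from the discrete spectral sum as the sigma_n2 start
  dk <- diff(c(0, spectrum$kappa[ok]))
  var_plugin <- sum(spectrum$density[ok] * spectrum$kappa[ok] * dk) / (2 * pi)
  start <- list(log_s2 = log(max(var_plugin, 1e-12)),
                outer_scale = extent / 4, exponent = 3)
  if (!is.null(init)) {
    if (!is.null(init$sigma_n2)) start$log_s2 <- log(init$sigma_n2)
    if (!is.null(init$outer_scale)) start$outer_scale <- init$outer_scale
    if (!is.null(init$exponent)) start$exponent <- init$exponent
  }
  lower <- c(log_s2 = -80, outer_scale = px, exponent = 1.01)
  upper <- c(log_s2 = 40, outer_scale = 10 * extent, exponent = 6)
  band <- attr(spectrum, "kappa_band")
  fit <- tryCatch(
    minpack.lm::nlsLM(
      logd ~ log(4 * pi) + log_s2 + 2 * log(outer_scale) +
        log(exponent - 1) - exponent * log(1 + kappa^2 * outer_scale^2),
      data = df, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(outer_scale = start$outer_scale,
                          exponent = start$exponent,
                          sigma_n2_fit = exp(start$log_s2),
                          residual_rms = NA_real_, converged = FALSE,
                          kappa_band = band),
                     class = "spectrum_fit"))
  }
  cf <- coef(fit)
  at_bound <- function(v, lo, hi) {
    (v - lo) < 1e-6 * max(1, abs(lo)) || (hi - v) < 1e-6 * max(1, abs(hi))
  }
  converged <- fit$convInfo$isConv &&
    !at_bound(cf[["outer_scale"]], px, 10 * extent) &&
    !at_bound(cf[["exponent"]], 1.01, 6)
  structure(list(outer_scale = unname(cf[["outer_scale"]]),
                 exponent = unname(cf[["exponent"]]),
                 sigma_n2_fit = exp(unname(cf[["log_s2"]])),
                 residual_rms = sqrt(mean(resid(fit)^2)),
                 converged = converged, kappa_band = band),
            class = "spectrum_fit")
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf(
    "<spectrum_fit> L0 = %.3g um, m = %.3f, sigma_n2 = %.3g, rms = %.3g, converged = %s\n",
    x$outer_scale, x$exponent, x$sigma_n2_fit, x$residual_rms, x$converged))
  invisible(x)
}

#' Fractal dimension
#'
#' Two estimators. `"spectral"`: the identity df = 4 - m applied to the
#' exponent of a converged Von Karman [fit_von_karman()] (an unconverged fit
#' yields `NA` with a warning). `"box_counting"`: the image is binarized by
#' Otsu's threshold on phi and the slope of log(occupied boxes) against
#' log(1/box size) is taken over dyadic box sizes from 2 to min(H, W)/4.
#'
#' @param input A `spectrum_fit` (spectral) or a [phase_image()] / matrix /
#'   logical mask (box counting).
#' @param method `"spectral"` or `"box_counting"`.
#' @return Scalar fractal dimension.
#' @export
#' @examples
#' fractal_dimension(
#'   structure(list(exponent = 1.3, converged = TRUE), class = "spectrum_fit"))
fractal_dimension <- function(input, method = c("spectral", "box_counting")) {
  method <- match.arg(method)
  if (method == "spectral") {
    if (!inherits(input, "spectrum_fit"))
      stop("spectral method requires a spectrum_fit")
    if (!isTRUE(input$converged)) {
      warning("unconverged spectrum fit: fractal dimension undefined")
      return(NA_real_)
    }
    return(4 - input$exponent)
  }
  mask <- binarize_otsu(input)
  box_counting_dimension(mask)
}

# Otsu threshold on the phase map, returning a logical foreground mask
binarize_otsu <- function(input) {
  m <- if (inherits(input, "phase_image")) input$phi else as.matrix(input)
  if (is.logical(m)) return(m)
  rng <- range(m)
  if (diff(rng) == 0) stop("constant image cannot be binarized")
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("box-counting binarization requires the EBImage package")
  scaled <- (m - rng[1]) / diff(rng)
  scaled > EBImage::otsu(scaled)
}

# slope of log(count) vs log(1/s) over dyadic box sizes 2 .. min(H,W)/4
box_counting_dimension <- function(mask) {
  stopifnot(is.logical(mask))
  smax <- min(dim(mask)) %/% 4
  if (smax < 2) stop("image too small for box counting")
  sizes <- 2^(1:floor(log2(smax)))
  if (length(sizes) < 2) stop("need at least two box sizes")
  counts <- vapply(sizes, function(s) {
    bi <- (row(mask) - 1L) %/% s
    bj <- (col(mask) - 1L) %/% s
    length(unique((bi * (max(bj) + 1L) + bj)[mask]))
  }, numeric(1))
  if (any(counts == 0)) return(0)
  unname(coef(lm(log(counts) ~ log(1 / sizes)))[2])
}
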