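# Independent brute-force oracles. Deliberately naive: explicit loops and a
# direct DFT-matrix transform, no shared code with the estimators they check.

oracle_gradient_square_mean <- function(phi, px) {
  h <- nrow(phi); w <- ncol(phi)
  acc <- 0
  for (i in 1:h) for (j in 1:w) {
    gx <- if (i == 1) phi[2, j] - phi[1, j]
          else if (i == h) phi[h, j] - phi[h - 1, j]
          else (phi[i + 1, j] - phi[i - 1, j]) / 2
    gy <- if (j == 1) phi[i, 2] - phi[i, 1]
          else if (j == w) phi[i, w] - phi[i, w - 1]
          else (phi[i, j + 1] - phi[i, j - 1]) / 2
    acc <- acc + (gx / px)^2 + (gy / px)^2
  }
  acc / (h * w)
}

oracle_phase_variance <- function(phi) {
  mu <- sum(phi) / length(phi)
  acc <- 0
  for (v in phi) acc <- acc + (v - mu)^2
  acc / length(phi)
}

oracle_anisotropy <- function(phi, px, lambda, outer_square = TRUE) {
  k0 <- 2 * pi / lambda
  x <- oracle_gradient_square_mean(phi, px) /
    (2 * k0^2 * oracle_phase_variance(phi))
  if (outer_square) (1 - x)^2 else 1 - x
}

# radial spectrum via explicit DFT matrices (no stats::fft) and a plain
# for-loop binning that mirrors the definition: log bins, DC excluded,
# band capped at 0.8 x angular Nyquist
oracle_radial_spectrum <- function(vals, px, nbins = 40L) {
  h <- nrow(vals); w <- ncol(vals)
  vals <- vals - mean(vals)
  W1 <- exp(-2i * pi * outer(0:(h - 1), 0:(h - 1)) / h)
  W2 <- exp(-2i * pi * outer(0:(w - 1), 0:(w - 1)) / w)
  P <- Mod(W1 %*% vals %*% W2)^2 * px^2 / (h * w)
  freq_idx <- function(n) c(0:(n / 2), -(n / 2 - 1):-1)
  kx <- 2 * pi * freq_idx(h) / (h * px)
  ky <- 2 * pi * freq_idx(w) / (w * px)
  kmax <- 0.8 * pi / px
  kmin <- 2 * pi / (max(h, w) * px)
  breaks <- exp(seq(log(kmin * 0.999), log(kmax), length.out = nbins + 1))
  ks <- numeric(nbins); ps <- numeric(nbins); cnt <- integer(nbins)
  for (i in 1:h) for (j in 1:w) {
    k <- sqrt(kx[i]^2 + ky[j]^2)
    if (k <= 0 || k > kmax) next
    b <- findInterval(k, breaks, rightmost.closed = TRUE)
    if (b < 1 || b > nbins) next
    ks[b] <- ks[b] + k; ps[b] <- ps[b] + P[i, j]; cnt[b] <- cnt[b] + 1L
  }
  ok <- cnt > 0
  list(kappa = ks[ok] / cnt[ok], density = ps[ok] / cnt[ok])
}

# hand ANOVA decomposition
oracle_anova_f <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}
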