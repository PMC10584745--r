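# FSIM: feature similarity index built on phase congruency (primary
# feature) and gradient magnitude (complementary feature), grayscale
# variant.

# Frequency-plane log-Gabor filter bank (radial x angular components).
# Returns a list of norient lists of nscale real filter masks.
log_gabor_bank <- function(nr, nc, nscale = 4, norient = 4,
                           min_wavelength = 6, mult = 2, sigma_onf = 0.55,
                           d_theta_on_sigma = 1.2) {
  fx <- (seq_len(nc) - 1) / nc; fx[fx > 0.5] <- fx[fx > 0.5] - 1
  fy <- (seq_len(nr) - 1) / nr; fy[fy > 0.5] <- fy[fy > 0.5] - 1
  FX <- matrix(fx, nr, nc, byrow = TRUE)
  FY <- matrix(fy, nr, nc)
  radius <- sqrt(FX^2 + FY^2); radius[1, 1] <- 1
  theta <- atan2(-FY, FX)
  lowpass <- 1 / (1 + (radius / 0.45)^30)   # suppress boundary frequencies
  sintheta <- sin(theta); costheta <- cos(theta)
  theta_sigma <- pi / norient / d_theta_on_sigma
  radial <- vector("list", nscale)
  for (s in seq_len(nscale)) {
    f0 <- 1 / (min_wavelength * mult^(s - 1))
    g <- exp(-(log(radius / f0))^2 / (2 * log(sigma_onf)^2)) * lowpass
    g[1, 1] <- 0
    radial[[s]] <- g
  }
  bank <- vector("list", norient)
  for (o in seq_len(norient)) {
    angl <- (o - 1) * pi / norient
    ds <- sintheta * cos(angl) - costheta * sin(angl)
    dc <- costheta * cos(angl) + sintheta * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * theta_sigma^2))
    bank[[o]] <- lapply(radial, function(g) g * spread)
  }
  bank
}

#' Phase congruency map
#'
#' Log-Gabor phase congruency (4 scales, 4 orientations by default):
#' orientation-wise phase-deviation-weighted energy normalized by the total
#' filter amplitude, summed over orientations. Values lie in `[0, 1]`.
#'
#' @param img numeric matrix.
#' @param nscale,norient number of filter scales and orientations.
#' @param min_wavelength wavelength of the finest-scale filter in pixels.
#' @param mult scale multiplier between successive filters.
#' @param sigma_onf bandwidth parameter of the radial log-Gabor.
#' @param noise_t fixed noise-energy threshold subtracted from the local
#'   energy before normalization (default 0).
#' @return matrix of phase congruency values.
#' @export
phase_congruency <- function(img, nscale = 4, norient = 4,
                             min_wavelength = 6, mult = 2, sigma_onf = 0.55,
                             noise_t = 0) {
  nr <- nrow(img); nc <- ncol(img)
  bank <- log_gabor_bank(nr, nc, nscale, norient, min_wavelength, mult,
                         sigma_onf)
  IM <- stats::fft(img)
  eps <- 1e-4
  total_energy <- matrix(0, nr, nc)
  total_an <- matrix(0, nr, nc)
  for (o in seq_len(norient)) {
    sumE <- matrix(0, nr, nc); sumO <- matrix(0, nr, nc)
    sumAn <- matrix(0, nr, nc)
    eo <- vector("list", nscale)
    for (s in seq_len(nscale)) {
      resp <- stats::fft(IM * bank[[o]][[s]], inverse = TRUE) / (nr * nc)
      eo[[s]] <- resp
      sumE <- sumE + Re(resp); sumO <- sumO + Im(resp)
      sumAn <- sumAn + Mod(resp)
    }
    xen <- sqrt(sumE^2 + sumO^2) + eps
    mE <- sumE / xen; mO <- sumO / xen
    energy <- matrix(0, nr, nc)
    for (s in seq_len(nscale)) {
      energy <- energy + Re(eo[[s]]) * mE + Im(eo[[s]]) * mO -
        abs(Re(eo[[s]]) * mO - Im(eo[[s]]) * mE)
    }
    total_energy <- total_energy + pmax(energy - noise_t, 0)
    total_an <- total_an + sumAn
  }
  total_energy / (total_an + eps)
}

# Scharr gradient magnitude.
gradient_magnitude <- function(img) {
  smooth <- c(3, 10, 3) / 16
  diffk <- c(1, 0, -1)
  gx <- filter_sep2(img, kx = diffk, ky = smooth)
  gy <- filter_sep2(img, kx = smooth, ky = diffk)
  sqrt(gx^2 + gy^2)
}

# Mean pooling downsample by integer factor f.
down_by <- function(m, f) {
  if (f <= 1) return(m)
  nr <- (nrow(m) %/% f) * f; nc <- (ncol(m) %/% f) * f
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  out <- matrix(0, nr %/% f, nc %/% f)
  for (i in seq_len(f)) for (j in seq_len(f)) {
    out <- out + m[seq(i, nr, f), seq(j, nc, f), drop = FALSE]
  }
  out / f^2
}

#' Feature similarity index (grayscale)
#'
#' Combines phase congruency similarity and Scharr gradient-magnitude
#' similarity (`T1 = 0.85`, `T2 = 160`), pooled with the pointwise maximum
#' phase congruency as weight. Images are first mean-pooled down so that
#' roughly 256 pixels span the smaller dimension, as in the original
#' formulation.
#'
#' @param pair an [image_pair()].
#' @param T1,T2 stabilization constants for the phase-congruency and
#'   gradient similarity terms.
#' @return FSIM score in `[0, 1]`; 1 for identical images.
#' @export
fsim <- function(pair, T1 = 0.85, T2 = 160) {
  m <- pair_matrices(pair)
  f <- max(1, round(min(dim(m$x)) / 256))
  x <- down_by(m$x, f); y <- down_by(m$y, f)
  pc1 <- phase_congruency(x); pc2 <- phase_congruency(y)
  g1 <- gradient_magnitude(x); g2 <- gradient_magnitude(y)
  s_pc <- (2 * pc1 * pc2 + T1) / (pc1^2 + pc2^2 + T1)
  s_g <- (2 * g1 * g2 + T2) / (g1^2 + g2^2 + T2)
  pcm <- pmax(pc1, pc2)
  tw <- sum(pcm)
  if (tw <= 0) return(mean(s_pc * s_g))  # featureless (constant) inputs
  sum(s_pc * s_g * pcm) / tw
}
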