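# IFC and VIF: information-theoretic metrics built on a Gaussian
# scale-mixture (GSM) channel model of multi-scale image coefficients.
#
# For each subband, local statistics over 3x3 neighborhoods estimate a
# per-coefficient gain g and additive distortion-channel noise sv^2 of the
# model D = g * C + V. IFC sums the mutual information between the source
# and distorted coefficients; VIF normalizes the information that the
# distorted image retains about the scene by the information the reference
# carries (both observed through additive HVS noise of variance sigma_nsq).

# Per-band information terms. Returns c(num, den): num is the
# distorted-channel information, den the reference information.
gsm_band_info <- function(xb, yb, sigma_nsq, win = 3) {
  if (min(dim(xb)) < win) return(c(num = 0, den = 0))
  eps <- 1e-10
  mu1 <- box_mean_valid(xb, win); mu2 <- box_mean_valid(yb, win)
  s11 <- pmax(box_mean_valid(xb * xb, win) - mu1^2, 0)
  s22 <- pmax(box_mean_valid(yb * yb, win) - mu2^2, 0)
  s12 <- box_mean_valid(xb * yb, win) - mu1 * mu2
  g <- s12 / (s11 + eps)
  sv <- s22 - g * s12
  g[s11 < eps] <- 0; sv[s11 < eps] <- s22[s11 < eps]
  sv[sv < eps] <- eps
  g[g < 0] <- 0
  c(num = sum(log2(1 + g^2 * s11 / (sv + sigma_nsq))),
    den = sum(log2(1 + s11 / sigma_nsq)))
}

# Subband pairs of a 4-level separable Haar decomposition (detail bands
# only); the mean is removed first so the approximation band is not needed.
wavelet_band_pairs <- function(x, y, levels = 4) {
  levels <- min(levels, max(1, floor(log2(min(dim(x)))) - 1))
  dx <- haar_dwt(x - mean(x), levels)
  dy <- haar_dwt(y - mean(y), levels)
  out <- list()
  for (j in seq_len(levels)) for (b in c("LH", "HL", "HH")) {
    out[[sprintf("L%d_%s", j, b)]] <- list(x = dx$detail[[j]][[b]],
                                           y = dy$detail[[j]][[b]])
  }
  out
}

# Pixel-domain pyramid band pairs (Gaussian low-pass residual scheme used
# by the pixel-domain VIF variant): scale s uses a window of side
# 2^(4-s+1)+1 after s-1 filter-and-downsample steps.
pixel_band_pairs <- function(x, y, scales = 4) {
  out <- list()
  for (s in seq_len(scales)) {
    N <- 2^(scales - s + 1) + 1
    k <- gauss_kernel(N / 5, radius = (N - 1) / 2)
    if (s > 1) {
      x <- filter_sep(x, k, "reflect"); y <- filter_sep(y, k, "reflect")
      x <- x[seq(1, nrow(x), 2), seq(1, ncol(x), 2), drop = FALSE]
      y <- y[seq(1, nrow(y), 2), seq(1, ncol(y), 2), drop = FALSE]
    }
    if (min(dim(x)) < N + 2) break
    mx <- filter_sep(x, k, "valid"); my <- filter_sep(y, k, "valid")
    r <- (N - 1) / 2
    xc <- x[(r + 1):(nrow(x) - r), (r + 1):(ncol(x) - r), drop = FALSE]
    yc <- y[(r + 1):(nrow(y) - r), (r + 1):(ncol(y) - r), drop = FALSE]
    out[[sprintf("S%d", s)]] <- list(x = xc - mx, y = yc - my)
  }
  out
}

#' Information fidelity criterion
#'
#' Sum over multi-scale subbands of the mutual information between
#' reference and distorted coefficients under the GSM channel model. The
#' score is non-negative, near zero when the distorted image is
#' independent of the reference, and grows with image size for identical
#' images.
#'
#' @param pair an [image_pair()].
#' @param levels number of decomposition levels (default 4).
#' @param eps_v stabilizing floor for the distortion-channel noise
#'   variance (default 1e-3); keeps the score finite on identical images.
#' @return IFC score with attribute `bands` (the per-band terms, which sum
#'   to the total).
#' @export
ifc <- function(pair, levels = 4, eps_v = 1e-3) {
  m <- pair_matrices(pair)
  bands <- wavelet_band_pairs(m$x, m$y, levels)
  per_band <- vapply(bands, function(b)
    gsm_band_info(b$x, b$y, sigma_nsq = eps_v)[["num"]], numeric(1))
  structure(sum(per_band), bands = per_band)
}

#' Visual information fidelity
#'
#' Ratio of the information the distorted image retains about the scene to
#' the information carried by the reference, both measured through
#' additive model noise of variance `sigma_nsq` (default 2). Identical
#' images score 1; the score can exceed 1 for contrast-enhanced inputs.
#' The default decomposition is wavelet-domain; `domain = "pixel"`
#' selects the pixel-domain pyramid variant.
#'
#' @param pair an [image_pair()].
#' @param sigma_nsq HVS model noise variance.
#' @param domain `"wavelet"` (default) or `"pixel"`.
#' @param levels decomposition levels / scales.
#' @return VIF score (>= 0).
#' @export
vif <- function(pair, sigma_nsq = 2, domain = c("wavelet", "pixel"),
                levels = 4) {
  domain <- match.arg(domain)
  m <- pair_matrices(pair)
  bands <- switch(domain,
    wavelet = wavelet_band_pairs(m$x, m$y, levels),
    pixel = pixel_band_pairs(m$x, m$y, levels))
  info <- vapply(bands, function(b) gsm_band_info(b$x, b$y, sigma_nsq),
                 numeric(2))
  num <- sum(info["num", ]); den <- sum(info["den", ])
  if (den <= 0) return(structure(1, bands = info))  # featureless reference
  structure(num / den, bands = info)
}
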