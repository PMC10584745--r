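# PSNR and the SSIM family (SSIM, MS-SSIM, IW-SSIM).
#
# All metrics take an image_pair of equal-shape 8-bit grayscale images and
# return a deterministic scalar where higher means better quality. Metrics
# that diverge on identical inputs (PSNR here; NQM and VSNR elsewhere) are
# capped at a configurable dB value and carry a `capped` attribute.

pair_matrices <- function(pair) {
  stopifnot(inherits(pair, "image_pair"))
  x <- pair$reference$pixels; y <- pair$distorted$pixels
  if (!identical(dim(x), dim(y))) stopf("pair images differ in shape")
  list(x = x + 0, y = y + 0)
}

capped_value <- function(value, cap, capped) {
  structure(value, capped = capped, cap = cap)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(255^2 / MSE)` in dB. A zero MSE (identical images) is
#' reported as the cap value with the `capped` attribute set.
#'
#' @param pair an [image_pair()].
#' @param cap dB value reported when MSE is zero (default 100).
#' @return PSNR in dB with attribute `capped`.
#' @export
psnr <- function(pair, cap = 100) {
  m <- pair_matrices(pair)
  mse <- mean((m$x - m$y)^2)
  if (mse == 0) return(capped_value(cap, cap, TRUE))
  capped_value(min(10 * log10(255^2 / mse), cap), cap, FALSE)
}

# Local SSIM statistics over a Gaussian window (valid region).
# Returns luminance (l), contrast-structure (cs) and full ssim maps.
ssim_maps <- function(x, y, win_size = 11, win_sigma = 1.5,
                      K1 = 0.01, K2 = 0.03, L = 255) {
  r <- (win_size - 1) / 2
  k <- gauss_kernel(win_sigma, radius = r)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mu1 <- filter_sep(x, k, "valid");  mu2 <- filter_sep(y, k, "valid")
  s11 <- filter_sep(x * x, k, "valid") - mu1^2
  s22 <- filter_sep(y * y, k, "valid") - mu2^2
  s12 <- filter_sep(x * y, k, "valid") - mu1 * mu2
  l <- (2 * mu1 * mu2 + C1) / (mu1^2 + mu2^2 + C1)
  cs <- (2 * s12 + C2) / (s11 + s22 + C2)
  list(l = l, cs = cs, ssim = l * cs)
}

#' Structural similarity index
#'
#' Mean-pooled local SSIM with an 11x11 Gaussian window (sigma 1.5),
#' `K1 = 0.01`, `K2 = 0.03`, dynamic range 255.
#'
#' @param pair an [image_pair()].
#' @param win_size,win_sigma Gaussian window size (odd) and SD.
#' @param K1,K2 stabilization constants.
#' @return SSIM score in `[-1, 1]`; 1 for identical images.
#' @export
ssim <- function(pair, win_size = 11, win_sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  m <- pair_matrices(pair)
  if (min(dim(m$x)) < win_size) stopf("image smaller than the SSIM window")
  mean(ssim_maps(m$x, m$y, win_size, win_sigma, K1, K2)$ssim)
}

#' Canonical MS-SSIM scale exponents
#' @export
MSSSIM_WEIGHTS <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)

# Shared MS-SSIM / IW-SSIM engine. weight_fun(x, y) either NULL (plain
# mean pooling) or a function returning a positive weight map matching the
# valid-region cs map (used by IW-SSIM).
msssim_core <- function(x, y, levels, weights, win_size, win_sigma, K1, K2,
                        weight_fun = NULL) {
  wpool <- function(map, w) {
    if (is.null(w)) return(mean(map))
    sum(map * w) / sum(w)
  }
  vals <- numeric(levels)
  for (j in seq_len(levels)) {
    sm <- ssim_maps(x, y, win_size, win_sigma, K1, K2)
    w <- if (is.null(weight_fun)) NULL else weight_fun(x, y, win_size)
    vals[j] <- if (j < levels) wpool(sm$cs, w) else wpool(sm$ssim, w)
    if (j < levels) { x <- down2(x); y <- down2(y) }
  }
  # negative pooled means cannot be raised to fractional exponents; clamp
  vals <- pmax(vals, 1e-6)
  prod(vals^weights)
}

msssim_levels <- function(dims, levels, win_size) {
  feasible <- max(1L, floor(log2(min(dims) / win_size)) + 1L)
  min(levels, feasible)
}

#' Multi-scale structural similarity
#'
#' Five dyadic scales (2x2 mean-filter downsampling) with the canonical
#' exponents; contrast/structure pooled at every scale, luminance only at
#' the coarsest. When the image is too small for the requested number of
#' scales (minimum size `win_size * 2^(levels-1)`), the scale count is
#' reduced automatically and the used exponents renormalized; the level
#' count actually used is reported in the `levels` attribute.
#'
#' @inheritParams ssim
#' @param levels requested number of scales (default 5).
#' @param weights per-scale exponents (default [MSSSIM_WEIGHTS]).
#' @return MS-SSIM score with attribute `levels`.
#' @export
ms_ssim <- function(pair, levels = 5, weights = MSSSIM_WEIGHTS,
                    win_size = 11, win_sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  m <- pair_matrices(pair)
  L <- msssim_levels(dim(m$x), levels, win_size)
  w <- weights[seq_len(L)] / sum(weights[seq_len(L)])
  structure(msssim_core(m$x, m$y, L, w, win_size, win_sigma, K1, K2),
            levels = L)
}

# Information-content weight map for IW-SSIM pooling. Local 3x3 statistics
# of both scale-j images feed a bivariate Gaussian model of (reference,
# distorted) patches observed through additive noise of variance
# `sigma_nsq`; the weight is the mutual information between the two noisy
# observations, which concentrates on textured, structurally shared
# regions and vanishes on flat background.
iw_weight_map <- function(x, y, win_size, sigma_nsq = 0.4) {
  mu1 <- box_mean_valid(x, 3); mu2 <- box_mean_valid(y, 3)
  s11 <- pmax(box_mean_valid(x * x, 3) - mu1^2, 0)
  s22 <- pmax(box_mean_valid(y * y, 3) - mu2^2, 0)
  s12 <- box_mean_valid(x * y, 3) - mu1 * mu2
  a <- s11 + sigma_nsq; b <- s22 + sigma_nsq
  w <- 0.5 * log2(a * b / pmax(a * b - s12^2, 1e-12)) + 1e-4
  # align the 3x3-valid stats map with the win_size-valid cs map
  off <- (win_size - 3) %/% 2
  nr <- nrow(w); nc <- ncol(w)
  w[(off + 1):(nr - off), (off + 1):(nc - off), drop = FALSE]
}

#' Information content weighted SSIM
#'
#' MS-SSIM local quality maps pooled with information-content weights
#' computed from a local Gaussian scale-mixture style model on 3x3
#' neighborhoods of each pyramid level (noise variance `sigma_nsq`,
#' default 0.4). With `uniform_weights = TRUE` the pooling degenerates to
#' plain mean pooling and the score equals [ms_ssim()].
#'
#' @inheritParams ms_ssim
#' @param sigma_nsq noise variance of the information-weight model.
#' @param uniform_weights force uniform pooling weights (degenerates to
#'   MS-SSIM; mainly for validation).
#' @return IW-SSIM score with attribute `levels`.
#' @export
iw_ssim <- function(pair, levels = 5, weights = MSSSIM_WEIGHTS,
                    win_size = 11, win_sigma = 1.5, K1 = 0.01, K2 = 0.03,
                    sigma_nsq = 0.4, uniform_weights = FALSE) {
  m <- pair_matrices(pair)
  L <- msssim_levels(dim(m$x), levels, win_size)
  w <- weights[seq_len(L)] / sum(weights[seq_len(L)])
  wf <- if (uniform_weights) NULL
        else function(x, y, ws) iw_weight_map(x, y, ws, sigma_nsq)
  structure(msssim_core(m$x, m$y, L, w, win_size, win_sigma, K1, K2, wf),
            levels = L)
}
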