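# Distortion simulation: Gaussian noise, Gaussian blur, and the full
# noise x blur study grid (five grades of each distortion applied singly
# and in combination to every reference).

#' Default distortion intensity grids
#'
#' Five grades of Gaussian noise (standard deviation in 8-bit gray levels)
#' and Gaussian blur (standard deviation in pixels).
#' @export
NOISE_LEVELS <- c(6, 9, 14, 21, 30)

#' @rdname NOISE_LEVELS
#' @export
BLUR_LEVELS <- c(0.6, 0.9, 1.4, 2.1, 3.0)

#' Distortion specification
#'
#' One cell of the distortion grid: a Gaussian-noise standard deviation (in
#' gray levels of the displayed 8-bit image), a Gaussian-blur standard
#' deviation (in pixels), and the RNG seed used for the noise realization.
#'
#' @param sigma_noise noise SD `>= 0`.
#' @param sigma_blur blur SD `>= 0`.
#' @param seed integer seed for the noise realization.
#' @return an object of class `distortion_spec`.
#' @export
distortion_spec <- function(sigma_noise, sigma_blur, seed = 0L) {
  if (sigma_noise < 0 || sigma_blur < 0) stopf("sigmas must be >= 0")
  structure(list(sigma_noise = as.numeric(sigma_noise),
                 sigma_blur = as.numeric(sigma_blur),
                 seed = as.integer(seed)),
            class = "distortion_spec")
}

#' Add i.i.d. zero-mean Gaussian noise to a display image
#'
#' Noise is added in floating point, then the result is clipped to
#' `[0, 255]` and rounded half-up. `sigma = 0` returns the input unchanged.
#'
#' @param img a `display_image`.
#' @param sigma noise standard deviation in gray levels (`>= 0`).
#' @param seed integer seed; the same seed reproduces the same realization.
#' @return a `display_image`.
#' @export
add_gaussian_noise <- function(img, sigma, seed = 0L) {
  stopifnot(inherits(img, "display_image"))
  if (sigma < 0) stopf("sigma must be >= 0")
  if (sigma == 0) return(img)
  px <- img$pixels
  noise <- with_seed(seed, matrix(stats::rnorm(length(px), 0, sigma),
                                  nrow(px), ncol(px)))
  out <- img
  out$pixels <- matrix(as.integer(round_half_up(clip(px + noise, 0, 255))),
                       nrow(px), ncol(px))
  out
}

#' Blur a display image with a Gaussian kernel
#'
#' Convolution with a normalized 2-D Gaussian truncated at radius
#' `ceiling(4 * sigma)`, reflect border handling, then rounding back to
#' 8-bit. `sigma = 0` is the identity.
#'
#' @param img a `display_image`.
#' @param sigma blur standard deviation in pixels (`>= 0`).
#' @return a `display_image`.
#' @export
apply_gaussian_blur <- function(img, sigma) {
  stopifnot(inherits(img, "display_image"))
  if (sigma < 0) stopf("sigma must be >= 0")
  if (sigma == 0) return(img)
  k <- gauss_kernel(sigma)
  out <- img
  sm <- filter_sep(img$pixels, k, boundary = "reflect")
  out$pixels <- matrix(as.integer(round_half_up(clip(sm, 0, 255))),
                       nrow(sm), ncol(sm))
  out
}

#' Apply one distortion specification
#'
#' When both distortions are present, blur is applied first and noise
#' second (system blur precedes detector noise); the order can be flipped
#' via `order = "noise_first"`.
#'
#' @param img reference `display_image`.
#' @param spec a [distortion_spec()].
#' @param order `"blur_first"` (default) or `"noise_first"`.
#' @return the distorted `display_image`.
#' @export
apply_distortion <- function(img, spec, order = c("blur_first", "noise_first")) {
  order <- match.arg(order)
  if (order == "blur_first") {
    add_gaussian_noise(apply_gaussian_blur(img, spec$sigma_blur),
                       spec$sigma_noise, spec$seed)
  } else {
    apply_gaussian_blur(add_gaussian_noise(img, spec$sigma_noise, spec$seed),
                        spec$sigma_blur)
  }
}

#' Reference/distorted image pair
#'
#' @param reference,distorted `display_image`s with identical dimensions,
#'   crop box and source id.
#' @param spec the [distortion_spec()] that produced `distorted`.
#' @return an object of class `image_pair`.
#' @export
image_pair <- function(reference, distorted, spec) {
  stopifnot(inherits(reference, "display_image"),
            inherits(distorted, "display_image"))
  if (!identical(dim(reference$pixels), dim(distorted$pixels)))
    stopf("reference and distorted images differ in shape")
  if (!identical(reference$source_id, distorted$source_id))
    stopf("reference and distorted images come from different sources")
  structure(list(reference = reference, distorted = distorted, spec = spec),
            class = "image_pair")
}

#' Generate the full distortion grid for a set of references
#'
#' For each reference: every noise level alone, every blur level alone, and
#' every noise x blur combination. With the default five-grade grids this
#' yields 35 pairs per reference (5 + 5 + 25), i.e. 210 pairs for six
#' references. Each pair receives a deterministic seed derived from
#' `(base_seed, source_id, sigma_noise, sigma_blur)`, so regenerating with
#' the same base seed is bit-identical while different base seeds change
#' only the noise realizations.
#'
#' @param references list of `display_image` references (already cropped).
#' @param noise_levels nonzero noise SDs (default [NOISE_LEVELS]).
#' @param blur_levels nonzero blur SDs (default [BLUR_LEVELS]).
#' @param base_seed integer base seed.
#' @param order combined-distortion order, see [apply_distortion()].
#' @return a list of `image_pair`s.
#' @export
generate_grid <- function(references, noise_levels = NOISE_LEVELS,
                          blur_levels = BLUR_LEVELS, base_seed = 1L,
                          order = "blur_first") {
  if (length(references) == 0) stopf("need at least one reference image")
  if (length(noise_levels) + length(blur_levels) == 0)
    stopf("need at least one distortion level")
  noise_levels <- noise_levels[noise_levels > 0]
  blur_levels <- blur_levels[blur_levels > 0]
  specs <- grid_specs(noise_levels, blur_levels)
  out <- vector("list", length(references) * nrow(specs))
  i <- 0L
  for (ref in references) {
    stopifnot(inherits(ref, "display_image"))
    for (s in seq_len(nrow(specs))) {
      sn <- specs$sigma_noise[s]; sb <- specs$sigma_blur[s]
      spec <- distortion_spec(sn, sb,
                              child_seed(base_seed, ref$source_id, sn, sb))
      i <- i + 1L
      out[[i]] <- image_pair(ref, apply_distortion(ref, spec, order), spec)
    }
  }
  out
}

# The per-reference grid as a data frame (noise-only, blur-only, combos).
grid_specs <- function(noise_levels = NOISE_LEVELS, blur_levels = BLUR_LEVELS) {
  noise_levels <- noise_levels[noise_levels > 0]
  blur_levels <- blur_levels[blur_levels > 0]
  rows <- rbind(
    if (length(noise_levels))
      data.frame(sigma_noise = noise_levels, sigma_blur = 0),
    if (length(blur_levels))
      data.frame(sigma_noise = 0, sigma_blur = blur_levels),
    if (length(noise_levels) && length(blur_levels))
      expand.grid(sigma_noise = noise_levels, sigma_blur = blur_levels,
                  KEEP.OUT.ATTRS = FALSE)
  )
  rownames(rows) <- NULL
  rows
}

#' Manifest describing a list of image pairs
#'
#' @param pairs list of `image_pair`s.
#' @return a data frame with one row per pair: `pair_id`, `source_id`,
#'   `sigma_noise`, `sigma_blur`, `seed`.
#' @export
pair_manifest <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(
      pair_id = sprintf("%s_n%g_b%g", p$reference$source_id,
                        p$spec$sigma_noise, p$spec$sigma_blur),
      source_id = p$reference$source_id,
      sigma_noise = p$spec$sigma_noise,
      sigma_blur = p$spec$sigma_blur,
      seed = p$spec$seed,
      stringsAsFactors = FALSE)
  }))
}
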