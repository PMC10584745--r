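# Synthetic CT phantom generator: deterministic head / chest / abdomen
# slices with site-plausible Hounsfield structure, used as reference
# images so the whole pipeline is testable without clinical data.

# Elliptical mask in normalized [-1, 1] coordinates.
ellipse_mask <- function(size, cx, cy, rx, ry, angle = 0) {
  u <- seq(-1, 1, length.out = size)
  X <- matrix(u, size, size, byrow = TRUE) - cx
  Y <- matrix(u, size, size) - cy
  if (angle != 0) {
    c_ <- cos(angle); s_ <- sin(angle)
    Xr <- X * c_ + Y * s_; Yr <- -X * s_ + Y * c_
    X <- Xr; Y <- Yr
  }
  (X / rx)^2 + (Y / ry)^2 <= 1
}

# Smooth Gaussian texture field with SD `sd` (gray/HU units) and spatial
# correlation length `scale` pixels.
texture_field <- function(size, sd, scale = 2) {
  if (sd <= 0) return(matrix(0, size, size))
  raw <- matrix(stats::rnorm(size^2), size, size)
  sm <- filter_sep(raw, gauss_kernel(scale), "reflect")
  sm * (sd / stats::sd(sm))
}

#' Generate a synthetic CT phantom slice
#'
#' Deterministic (given `seed`) site-specific phantom: a body ellipse with
#' a visible skin/muscle rim plus internal structures -- head: skull ring,
#' brain parenchyma with ventricles; chest: two low-attenuation lung
#' fields with vessel-like texture, heart and spine; abdomen: liver,
#' kidneys, aorta, bowel gas, subcutaneous fat and spine. Values are
#' stored as `HU + hu_offset`; pixels outside the body are stored as 0
#' (out-of-scan-field padding), so they fall to display value 0 under any
#' clinical window. The body mask and the main region masks are attached
#' as the `masks` attribute.
#'
#' @param site `"head"`, `"chest"` or `"abdomen"`.
#' @param size square image size in pixels (default 512, minimum 64).
#' @param seed integer seed for the texture fields.
#' @param texture_scale multiplier on all texture SDs (default 1).
#' @param hu_offset HU storage offset (default 32768).
#' @param id image identifier; defaults to `"<site>_phantom"`.
#' @return a [raw_ct_image()] with attribute `masks` (list of logical
#'   matrices: `body` plus site-specific regions).
#' @export
make_phantom <- function(site, size = 512, seed = 1, texture_scale = 1,
                         hu_offset = 32768L, id = paste0(site, "_phantom")) {
  site <- match.arg(site, CT_SITES)
  if (size < 64) stopf("phantom size must be >= 64")
  with_seed(seed, {
    hu <- matrix(NA_real_, size, size)
    masks <- list()
    ts <- texture_scale
    em <- function(...) ellipse_mask(size, ...)
    if (site == "head") {
      body <- em(0, 0, 0.66, 0.8)
      skull_out <- em(0, 0, 0.62, 0.76)
      skull_in <- em(0, 0, 0.56, 0.7)
      brain <- em(0, 0, 0.52, 0.66)
      hu[body] <- 45                            # scalp / muscle rim
      hu[skull_out & !skull_in] <- 1000         # skull ring
      hu[skull_in] <- 60                        # inner table / dura
      hu[brain] <- 38 + texture_field(size, 4 * ts)[brain]
      gm <- em(0, 0, 0.45, 0.58) & !em(0, 0, 0.34, 0.47)
      hu[gm & brain] <- hu[gm & brain] + 6      # cortical gray matter band
      vent <- em(-0.1, -0.05, 0.07, 0.2) | em(0.1, -0.05, 0.07, 0.2)
      hu[vent & brain] <- 8                     # CSF ventricles
      masks$brain <- brain; masks$ventricles <- vent & brain
    } else if (site == "chest") {
      body <- em(0, 0.05, 0.9, 0.68)
      hu[body] <- 35 + texture_field(size, 6 * ts)[body]
      lungL <- em(-0.42, 0, 0.32, 0.45, angle = 0.15)
      lungR <- em(0.42, 0, 0.34, 0.48, angle = -0.15)
      lung <- (lungL | lungR) & body
      hu[lung] <- -850 + texture_field(size, 25 * ts, scale = 1.5)[lung]
      # vessel-like bright puncta inside the lungs
      idx <- which(lung)
      vess <- sample(idx, max(10, length(idx) %/% 150))
      vmap <- matrix(0, size, size); vmap[vess] <- 1
      vmap <- filter_sep(vmap, gauss_kernel(1), "reflect")
      hu[lung] <- hu[lung] + 900 * (vmap[lung] / max(vmap))
      heart <- em(0, 0.12, 0.2, 0.24) & body & !lung
      hu[heart] <- 45 + texture_field(size, 4 * ts)[heart]
      spine <- em(0, 0.52, 0.09, 0.11) & body
      hu[spine] <- 700
      masks$lung <- lung
      masks$body_wall <- body & !lung & !spine
      masks$spine <- spine
    } else {
      body <- em(0, 0, 0.85, 0.66)
      inner <- em(0, 0, 0.78, 0.59)
      hu[body] <- -90 + texture_field(size, 5 * ts)[body]   # subcutaneous fat
      rim <- body & !em(0, 0, 0.82, 0.63)
      hu[rim] <- 45                                        # skin / muscle rim
      hu[inner] <- 30 + texture_field(size, 5 * ts)[inner] # soft tissue
      liver <- em(-0.32, -0.12, 0.34, 0.3) & inner
      hu[liver] <- 60 + texture_field(size, 4 * ts)[liver]
      kidneyL <- em(-0.3, 0.3, 0.1, 0.14) & inner
      kidneyR <- em(0.3, 0.3, 0.1, 0.14) & inner
      hu[kidneyL | kidneyR] <- 35
      aorta <- em(0, 0.22, 0.05, 0.05) & inner
      hu[aorta] <- 45
      gas <- em(0.3, -0.25, 0.12, 0.1) & inner
      hu[gas] <- -600                                      # bowel gas
      spine <- em(0, 0.42, 0.09, 0.1) & inner
      hu[spine] <- 700
      masks$liver <- liver; masks$spine <- spine; masks$gas <- gas
    }
    masks$body <- body
    hu <- clip(hu, -1024, 3071)
    stored <- matrix(0, size, size)
    stored[body] <- hu[body] + hu_offset
    stored <- clip(stored, 0, 65535)
    out <- raw_ct_image(stored, site = site, hu_offset = hu_offset, id = id)
    attr(out, "masks") <- masks
    out
  })
}

# Bounding box (half-open, crop_background convention) of a logical mask.
mask_bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0); cols <- which(colSums(mask) > 0)
  as.integer(c(min(rows), min(cols), max(rows) + 1L, max(cols) + 1L))
}
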