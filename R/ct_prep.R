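# CT image preparation: raw 16-bit storage, window/level display conversion,
# and automatic background cropping.

CT_SITES <- c("head", "chest", "abdomen")

# Clinical window width/level (HU) per anatomical site.
SITE_WINDOWS <- list(
  head    = c(width = 80,   level = 40),
  chest   = c(width = 1500, level = -650),
  abdomen = c(width = 350,  level = 40)
)

#' Construct a raw CT image
#'
#' A raw CT image is a rectangular grid of unsigned 16-bit stored values
#' together with the convention that `stored = HU + hu_offset` (DeepLesion
#' style unsigned PNGs use `hu_offset = 32768`).
#'
#' @param pixels integer matrix with values in `[0, 65535]`.
#' @param site anatomical site, one of `"head"`, `"chest"`, `"abdomen"`.
#' @param hu_offset integer added to Hounsfield units at storage time.
#' @param id image identifier string.
#' @return an object of class `raw_ct_image`.
#' @export
raw_ct_image <- function(pixels, site, hu_offset = 32768L, id = "img") {
  if (!is.matrix(pixels) || nrow(pixels) < 1 || ncol(pixels) < 1)
    stopf("pixels must be a non-empty matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 65535)
    stopf("pixel values must lie in [0, 65535]")
  site <- match.arg(site, CT_SITES)
  structure(
    list(pixels = matrix(as.integer(pixels), nrow(pixels), ncol(pixels)),
         site = site, hu_offset = as.integer(hu_offset), id = as.character(id)),
    class = "raw_ct_image")
}

#' @export
print.raw_ct_image <- function(x, ...) {
  cat(sprintf("<raw_ct_image '%s'> %dx%d, site=%s, hu_offset=%d, stored range [%d, %d]\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$site, x$hu_offset,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Window setting
#'
#' @param width window width in HU (must be positive).
#' @param level window level (center) in HU.
#' @return an object of class `window_setting`.
#' @export
window_setting <- function(width, level) {
  if (!is.numeric(width) || width <= 0) stopf("window width must be > 0")
  structure(list(width = as.numeric(width), level = as.numeric(level)),
            class = "window_setting")
}

#' Default clinical window for a site
#'
#' Head 80/40, chest 1500/-650, abdomen 350/40 (width/level in HU).
#'
#' @param site anatomical site label.
#' @return a [window_setting()].
#' @export
site_window <- function(site) {
  site <- match.arg(site, CT_SITES)
  w <- SITE_WINDOWS[[site]]
  window_setting(w["width"], w["level"])
}

# Internal display-image constructor; pixels already integer in [0,255].
new_display_image <- function(pixels, window, source_id, crop_box = NULL,
                              no_foreground = FALSE) {
  structure(list(pixels = matrix(as.integer(pixels), nrow(pixels), ncol(pixels)),
                 window = window, source_id = as.character(source_id),
                 crop_box = crop_box, no_foreground = isTRUE(no_foreground)),
            class = "display_image")
}

#' @export
print.display_image <- function(x, ...) {
  cb <- if (is.null(x$crop_box)) "none"
        else paste(x$crop_box, collapse = ",")
  cat(sprintf("<display_image '%s'> %dx%d, window %g/%g, crop_box=[%s]\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels),
              x$window$width, x$window$level, cb))
  invisible(x)
}

#' Read a raw CT image from a grayscale PNG
#'
#' Accepts 8- or 16-bit single-channel PNGs. Stored values are preserved
#' exactly (an 8-bit file yields values in `[0, 255]`; no rescaling to the
#' 16-bit range is performed).
#'
#' @param path path to the PNG file.
#' @param site anatomical site label.
#' @param hu_offset integer HU storage offset (`stored = HU + hu_offset`).
#' @param id image identifier; defaults to the file name without extension.
#' @return a [raw_ct_image()].
#' @export
load_raw_png <- function(path, site, hu_offset = 32768L, id = NULL) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  img <- tryCatch(png::readPNG(path, info = TRUE),
                  error = function(e) stopf("cannot decode '%s' as PNG: %s",
                                            path, conditionMessage(e)))
  if (length(dim(img)) != 2)
    stopf("'%s' is not single-channel grayscale (dims: %s)",
          path, paste(dim(img), collapse = "x"))
  depth <- attr(img, "info")$bit.depth
  if (is.null(depth)) depth <- 8L
  stored <- round_half_up(img * (2^depth - 1))
  if (is.null(id)) id <- sub("\\.[Pp][Nn][Gg]$", "", basename(path))
  raw_ct_image(stored, site = site, hu_offset = hu_offset, id = id)
}

#' Write a raw CT image as a 16-bit grayscale PNG
#'
#' @param raw a [raw_ct_image()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_raw_png <- function(raw, path) {
  stopifnot(inherits(raw, "raw_ct_image"))
  write_png16(raw$pixels, path)
}

#' Convert a raw CT image to an 8-bit display image
#'
#' Linear window/level mapping: with `HU = stored - hu_offset`, the display
#' value is `255 * (HU - (level - width/2)) / width`, clipped to `[0, 255]`
#' and rounded half-up. The HU interval `[level - width/2, level + width/2]`
#' therefore maps exactly onto `[0, 255]`.
#'
#' @param raw a [raw_ct_image()].
#' @param window a [window_setting()]; defaults to the site's clinical window.
#' @return a `display_image`.
#' @export
window_to_display <- function(raw, window = site_window(raw$site)) {
  stopifnot(inherits(raw, "raw_ct_image"))
  if (!inherits(window, "window_setting")) stopf("window must be a window_setting")
  hu <- raw$pixels - raw$hu_offset
  v <- 255 * (hu - (window$level - window$width / 2)) / window$width
  new_display_image(round_half_up(clip(v, 0, 255)), window, raw$id)
}

# 3x3 binary dilation / erosion by index shifting (used for closing).
.shift_or <- function(m, combine) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r <- clip(seq_len(nr) + dr, 1L, nr)
    c <- clip(seq_len(nc) + dc, 1L, nc)
    out <- combine(out, m[r, c, drop = FALSE])
  }
  out
}

#' Crop a display image to its main foreground object
#'
#' Foreground is `pixels >= threshold` after an optional 3x3 morphological
#' closing; the crop is the bounding box of the largest connected component
#' (8-connectivity) expanded by `margin` pixels and clipped to the image.
#' The box is recorded half-open as `(row0, col0, row1, col1)` with 1-based
#' inclusive start and exclusive end, so the same box can be applied to the
#' matching reference or distorted image with [apply_crop_box()].
#'
#' @param img a `display_image`.
#' @param threshold 8-bit foreground threshold (default 10).
#' @param margin margin in pixels added around the bounding box (default 2).
#' @param closing apply a 3x3 morphological closing before labelling.
#' @return a cropped `display_image`; if no pixel reaches the threshold the
#'   full image is returned with the `no_foreground` flag set (and a warning).
#' @export
crop_background <- function(img, threshold = 10, margin = 2, closing = TRUE) {
  stopifnot(inherits(img, "display_image"))
  fg <- img$pixels >= threshold
  if (!any(fg)) {
    warning("no foreground pixel at threshold ", threshold,
            "; returning full image", call. = FALSE)
    out <- img
    out$crop_box <- c(1L, 1L, nrow(img$pixels) + 1L, ncol(img$pixels) + 1L)
    out$no_foreground <- TRUE
    return(out)
  }
  if (closing) {
    fg <- .shift_or(fg, `|`)   # dilate
    fg <- .shift_or(fg, `&`)   # erode
  }
  lab <- EBImage::bwlabel(fg * 1L)
  lab <- matrix(as.integer(lab), nrow(fg), ncol(fg))
  if (max(lab) == 0L) {
    # closing can only grow the mask, but guard anyway
    keep <- fg
  } else {
    sizes <- tabulate(lab[lab > 0L])
    keep <- lab == which.max(sizes)
  }
  rows <- which(rowSums(keep) > 0)
  cols <- which(colSums(keep) > 0)
  r0 <- max(1L, min(rows) - margin); r1 <- min(nrow(fg), max(rows) + margin)
  c0 <- max(1L, min(cols) - margin); c1 <- min(ncol(fg), max(cols) + margin)
  box <- as.integer(c(r0, c0, r1 + 1L, c1 + 1L))
  apply_crop_box(img, box)
}

#' Apply a previously computed crop box
#'
#' @param img a `display_image`.
#' @param box half-open integer box `(row0, col0, row1, col1)` as produced by
#'   [crop_background()].
#' @return the cropped `display_image` with `crop_box` recorded.
#' @export
apply_crop_box <- function(img, box) {
  stopifnot(inherits(img, "display_image"), length(box) == 4)
  box <- as.integer(box)
  if (box[1] < 1 || box[2] < 1 || box[3] > nrow(img$pixels) + 1L ||
      box[4] > ncol(img$pixels) + 1L || box[3] <= box[1] || box[4] <= box[2])
    stopf("crop box [%s] outside image bounds or degenerate",
          paste(box, collapse = ","))
  out <- img
  out$pixels <- img$pixels[box[1]:(box[3] - 1L), box[2]:(box[4] - 1L), drop = FALSE]
  out$crop_box <- box
  out
}
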