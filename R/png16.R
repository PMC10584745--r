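# Minimal 16-bit grayscale PNG encoder.
#
# png::writePNG always stores 8 bits per sample, which silently destroys the
# precision of raw CT grids. The PNG container for a single-channel 16-bit
# image is small enough to emit directly: IHDR, one zlib-compressed IDAT
# with filter-type-0 scanlines (big-endian samples), and IEND.

.crc32_table <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit pattern
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(bitwShiftR(c, 1L), poly)
           else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  tab
})

.crc32 <- function(bytes) {
  crc <- -1L
  ints <- as.integer(bytes)
  for (b in ints) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwShiftR(crc, 8L), .crc32_table[idx + 1L])
  }
  bitwXor(crc, -1L)
}

.u32be <- function(x) {
  # x may exceed .Machine$integer.max when given as the unsigned value
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

.png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- .crc32(body)
  crc_u <- if (crc < 0) crc + 4294967296 else crc
  c(.u32be(length(data)), body, .u32be(crc_u))
}

# pixels: integer matrix in [0, 65535]; rows are image rows.
write_png16 <- function(pixels, path) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  ihdr <- c(.u32be(nc), .u32be(nr),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, grayscale
  v <- as.integer(t(pixels))                 # row-major scanline order
  hi <- as.raw(v %/% 256L); lo <- as.raw(v %% 256L)
  samples <- as.raw(rbind(hi, lo))           # big-endian interleave
  dim(samples) <- NULL
  scan <- matrix(samples, nrow = 2L * nc)
  idat_raw <- as.raw(rbind(matrix(as.raw(0L), 1L, nr), scan))  # filter byte 0
  dim(idat_raw) <- NULL
  idat <- memCompress(idat_raw, type = "gzip")  # zlib stream
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           .png_chunk("IHDR", ihdr),
           .png_chunk("IDAT", idat),
           .png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
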