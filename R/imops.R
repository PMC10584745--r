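# Low-level image operations shared by the distortion and metric code:
# border padding, separable correlation, Gaussian kernels, dyadic
# downsampling and a separable Haar DWT. All operate on plain numeric
# matrices.

# Padding index vector for a dimension of size n and radius r.
#   reflect:   d c b a | a b c d | d c b a   (edge repeated)
#   symmetric: alias of reflect
#   replicate: a a a a | a b c d | d d d d
pad_idx <- function(n, r, type = c("reflect", "replicate")) {
  type <- match.arg(type)
  if (r == 0) return(seq_len(n))
  left <- switch(type,
    reflect = rev(seq_len(min(r, n))),
    replicate = rep(1L, r))
  right <- switch(type,
    reflect = rev(n + 1L - seq_len(min(r, n))),
    replicate = rep(n, r))
  # for reflect with r > n, tile the reflection (never needed at our sizes,
  # but keep the call total length correct)
  while (length(left) < r) left <- c(left[1], left)
  while (length(right) < r) right <- c(right, right[length(right)])
  c(left, seq_len(n), right)
}

pad_matrix <- function(m, r, type = "reflect") {
  m[pad_idx(nrow(m), r, type), pad_idx(ncol(m), r, type), drop = FALSE]
}

# Separable correlation with (possibly different) odd-length kernels along
# the horizontal (kx) and vertical (ky) directions. boundary "valid"
# shrinks the output by each kernel's radius on the matching sides.
filter_sep2 <- function(m, kx, ky = kx,
                        boundary = c("reflect", "replicate", "valid")) {
  boundary <- match.arg(boundary)
  stopifnot(length(kx) %% 2 == 1, length(ky) %% 2 == 1)
  rx <- (length(kx) - 1L) %/% 2L
  ry <- (length(ky) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  pad_type <- if (boundary == "valid") "reflect" else boundary
  p <- m[pad_idx(nr, ry, pad_type), pad_idx(nc, rx, pad_type), drop = FALSE]
  # horizontal pass
  if (rx > 0) {
    tmp <- matrix(0, nrow(p), nc)
    for (t in seq_along(kx))
      tmp <- tmp + kx[t] * p[, t:(t + nc - 1L), drop = FALSE]
  } else tmp <- p * kx
  # vertical pass
  if (ry > 0) {
    out <- matrix(0, nr, nc)
    for (t in seq_along(ky))
      out <- out + ky[t] * tmp[t:(t + nr - 1L), , drop = FALSE]
  } else out <- tmp * ky
  if (boundary == "valid") {
    if (nr <= 2 * ry || nc <= 2 * rx) stopf("image too small for valid filtering")
    out <- out[(ry + 1L):(nr - ry), (rx + 1L):(nc - rx), drop = FALSE]
  }
  out
}

# Same kernel along both directions.
filter_sep <- function(m, k, boundary = "reflect") {
  filter_sep2(m, kx = k, ky = k, boundary = boundary)
}

# Sampled, normalized 1-D Gaussian of standard deviation sigma.
gauss_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 2x2 mean filter + stride-2 subsampling (dyadic pyramid step). Odd trailing
# rows/columns are dropped after replicate padding to even size.
down2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr %% 2 == 1) m <- m[c(seq_len(nr), nr), , drop = FALSE]
  if (nc %% 2 == 1) m <- m[, c(seq_len(nc), nc), drop = FALSE]
  nr <- nrow(m); nc <- ncol(m)
  (m[seq(1, nr, 2), seq(1, nc, 2), drop = FALSE] +
   m[seq(2, nr, 2), seq(1, nc, 2), drop = FALSE] +
   m[seq(1, nr, 2), seq(2, nc, 2), drop = FALSE] +
   m[seq(2, nr, 2), seq(2, nc, 2), drop = FALSE]) / 4
}

# Local moving-window mean with an all-ones (box) kernel, valid region.
box_mean_valid <- function(m, side) {
  k <- rep(1 / side, side)
  filter_sep(m, k, boundary = "valid")
}

# One separable Haar analysis step: returns list(LL, LH, HL, HH) at half
# resolution. Odd sizes are replicate-padded to even first.
haar_step <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr %% 2 == 1) m <- m[c(seq_len(nr), nr), , drop = FALSE]
  if (nc %% 2 == 1) m <- m[, c(seq_len(nc), nc), drop = FALSE]
  s <- sqrt(2) / 2
  ro <- m[seq(1, nrow(m), 2), , drop = FALSE]
  re <- m[seq(2, nrow(m), 2), , drop = FALSE]
  lo_r <- s * (ro + re); hi_r <- s * (ro - re)
  co <- function(x) x[, seq(1, ncol(x), 2), drop = FALSE]
  ce <- function(x) x[, seq(2, ncol(x), 2), drop = FALSE]
  list(LL = s * (co(lo_r) + ce(lo_r)), LH = s * (co(lo_r) - ce(lo_r)),
       HL = s * (co(hi_r) + ce(hi_r)), HH = s * (co(hi_r) - ce(hi_r)))
}

# Multi-level separable Haar DWT. Returns a list with one element per level,
# each holding LH/HL/HH detail bands, plus the final LL approximation.
haar_dwt <- function(m, levels) {
  out <- vector("list", levels)
  cur <- m
  for (j in seq_len(levels)) {
    st <- haar_step(cur)
    out[[j]] <- st[c("LH", "HL", "HH")]
    cur <- st$LL
  }
  list(detail = out, approx = cur)
}
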