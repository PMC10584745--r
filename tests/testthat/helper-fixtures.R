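# Shared fixtures: tiny display images and pairs built in code.

display_from_matrix <- function(m, id = "fix") {
  raw <- raw_ct_image(m, site = "head", hu_offset = 0L, id = id)
  # identity window over the stored 8-bit range: width 255, level 127.5
  window_to_display(raw, window_setting(255, 127.5))
}

random_display <- function(n, seed = 1, id = "rand") {
  m <- ctfriqa:::with_seed(seed, matrix(sample(0:255, n * n, TRUE), n, n))
  display_from_matrix(m, id)
}

make_pair <- function(ref, dist = ref, sn = 0, sb = 0, seed = 0L) {
  image_pair(ref, dist, distortion_spec(sn, sb, seed))
}

# A small cropped phantom reference (cached per site/size across tests).
phantom_ref <- local({
  cache <- list()
  function(site = "chest", size = 128, seed = 5) {
    key <- paste(site, size, seed)
    if (is.null(cache[[key]])) {
      ph <- make_phantom(site, size = size, seed = seed)
      cache[[key]] <<- crop_background(window_to_display(ph), margin = 2)
    }
    cache[[key]]
  }
})

# Brute-force windowed SSIM oracle: explicit loop over every valid 11x11
# window with Gaussian weights, independent of the filtering implementation.
ssim_bruteforce <- function(x, y, win = 11, sigma = 1.5,
                            K1 = 0.01, K2 = 0.03, L = 255) {
  g <- exp(-((-(win %/% 2)):(win %/% 2))^2 / (2 * sigma^2))
  w <- outer(g, g); w <- w / sum(w)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  vals <- c()
  for (i in seq_len(nrow(x) - win + 1)) {
    for (j in seq_len(ncol(x) - win + 1)) {
      xs <- x[i:(i + win - 1), j:(j + win - 1)]
      ys <- y[i:(i + win - 1), j:(j + win - 1)]
      mu1 <- sum(w * xs); mu2 <- sum(w * ys)
      s1 <- sum(w * xs^2) - mu1^2; s2 <- sum(w * ys^2) - mu2^2
      s12 <- sum(w * xs * ys) - mu1 * mu2
      vals <- c(vals, (2 * mu1 * mu2 + C1) * (2 * s12 + C2) /
                  ((mu1^2 + mu2^2 + C1) * (s1 + s2 + C2)))
    }
  }
  mean(vals)
}

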