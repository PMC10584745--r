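identical_pair <- function(size = 96, site = "chest") {
  ref <- phantom_ref(site, size)
  make_pair(ref, ref)
}

noisy_pair <- function(sn = 0, sb = 0, size = 128, site = "chest", seed = 17) {
  ref <- phantom_ref(site, size)
  make_pair(ref, apply_distortion(ref, distortion_spec(sn, sb, seed)), sn, sb)
}

test_that("every metric returns its perfect score on identical images", {
  pair <- identical_pair()
  v <- compute_all(pair)
  expect_length(v$scores, 9)
  expect_false(anyNA(v$scores))
  for (nm in c("SSIM", "FSIM", "VIF", "MSSSIM", "IWSSIM"))
    expect_equal(unname(v$scores[nm]), 1, tolerance = 1e-9)
  for (nm in c("PSNR", "NQM", "VSNR")) {
    expect_equal(unname(v$scores[nm]), 100)
    expect_true(v$capped[nm])
  }
  expect_gt(v$scores["IFC"], 10)
  expect_false(any(v$capped[c("SSIM", "FSIM", "VIF", "MSSSIM", "IWSSIM")]))
})

test_that("PSNR equals its closed form exactly and caps at zero MSE", {
  ref <- display_from_matrix(matrix(0L, 2, 2))
  dst <- display_from_matrix(matrix(c(10L, 0L, 0L, 0L), 2, 2))
  p <- psnr(make_pair(ref, dst))
  expect_identical(as.numeric(p), 10 * log10(255^2 / 25))
  expect_false(attr(p, "capped"))
  p0 <- psnr(make_pair(ref, ref))
  expect_identical(as.numeric(p0), 100)
  expect_true(attr(p0, "capped"))
})

test_that("PSNR decreases strictly along the noise grid", {
  vals <- vapply(NOISE_LEVELS, function(sn)
    as.numeric(psnr(noisy_pair(sn, seed = ctfriqa:::child_seed(2, sn)))),
    numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("SSIM matches the brute-force windowed oracle", {
  for (seed in 1:3) {
    x <- random_display(16, seed = seed)
    y <- random_display(16, seed = seed + 50)
    expect_equal(ssim(make_pair(x, y)),
                 ssim_bruteforce(x$pixels + 0, y$pixels + 0),
                 tolerance = 1e-9)
  }
  x <- random_display(32, seed = 9)
  y <- add_gaussian_noise(x, 14, seed = 10)
  expect_equal(ssim(make_pair(x, y)),
               ssim_bruteforce(x$pixels + 0, y$pixels + 0),
               tolerance = 1e-9)
})

test_that("SSIM penalizes a pure luminance shift", {
  a <- display_from_matrix(matrix(100L, 32, 32))
  b <- display_from_matrix(matrix(110L, 32, 32))
  expect_lt(ssim(make_pair(a, b)), 1)
  expect_equal(ssim(make_pair(a, a)), 1)
})

test_that("MS-SSIM degenerates to SSIM at a single scale", {
  x <- random_display(64, seed = 4)
  y <- add_gaussian_noise(x, 9, seed = 5)
  pair <- make_pair(x, y)
  expect_equal(as.numeric(ms_ssim(pair, levels = 1, weights = 1)),
               ssim(pair), tolerance = 1e-9)
  expect_equal(as.numeric(ms_ssim(identical_pair())), 1)
})

test_that("MS-SSIM reduces the scale count for small images", {
  x <- random_display(32, seed = 6)
  y <- add_gaussian_noise(x, 6, seed = 7)
  s <- ms_ssim(make_pair(x, y))
  expect_equal(attr(s, "levels"), 2)  # 11 * 2^(L-1) <= 32 allows L = 2
  big <- ms_ssim(noisy_pair(9, size = 256))
  expect_equal(attr(big, "levels"), 5)
})

test_that("IW-SSIM with uniform weights equals MS-SSIM", {
  pair <- noisy_pair(14, 0.9)
  expect_equal(as.numeric(iw_ssim(pair, uniform_weights = TRUE)),
               as.numeric(ms_ssim(pair)), tolerance = 1e-6)
  expect_equal(as.numeric(iw_ssim(identical_pair())), 1)
})

test_that("information weights concentrate on textured regions", {
  flat <- matrix(128, 64, 64)
  tex <- flat
  tex[, 33:64] <- 128 + ctfriqa:::with_seed(8, matrix(rnorm(64 * 32, 0, 30),
                                                      64, 32))
  tex <- pmin(pmax(round(tex), 0), 255)
  w <- ctfriqa:::iw_weight_map(tex, tex, win_size = 11)
  half <- ncol(w) %/% 2
  expect_gt(sum(w[, (half + 1):ncol(w)]), 2 * sum(w[, 1:half]))
})

test_that("FSIM is symmetric, bounded, and perfect on identical inputs", {
  expect_equal(fsim(identical_pair()), 1, tolerance = 1e-9)
  for (seed in c(3, 13)) {
    x <- random_display(64, seed = seed)
    y <- add_gaussian_noise(x, 21, seed = seed + 1)
    f_xy <- fsim(make_pair(x, y))
    f_yx <- fsim(make_pair(y, x))
    expect_equal(f_xy, f_yx, tolerance = 1e-12)
    expect_gte(f_xy, 0); expect_lte(f_xy, 1)
  }
})

test_that("IFC is additive over bands and vanishes for independent noise", {
  pair <- noisy_pair(14)
  total <- ifc(pair)
  expect_equal(as.numeric(total), sum(attr(total, "bands")), tolerance = 1e-9)

  ref <- phantom_ref("chest", 128)
  dims <- dim(ref$pixels)
  noise <- display_from_matrix(
    ctfriqa:::with_seed(99, matrix(pmin(pmax(round(rnorm(prod(dims), 128, 50)),
                                             0), 255), dims[1], dims[2])))
  noise$source_id <- ref$source_id
  indep <- as.numeric(ifc(image_pair(ref, noise, distortion_spec(30, 0))))
  ident <- as.numeric(ifc(make_pair(ref, ref)))
  expect_lt(indep / ident, 0.05)
})

test_that("IFC on identical images grows with image size", {
  small <- as.numeric(ifc(make_pair(phantom_ref("head", 64),
                                    phantom_ref("head", 64))))
  large <- as.numeric(ifc(make_pair(phantom_ref("head", 128),
                                    phantom_ref("head", 128))))
  expect_gt(large, small)
})

test_that("VIF is 1 on identical images and decays with noise", {
  expect_equal(as.numeric(vif(identical_pair())), 1, tolerance = 1e-9)
  v6 <- as.numeric(vif(noisy_pair(6, seed = 31)))
  v30 <- as.numeric(vif(noisy_pair(30, seed = 32)))
  expect_lt(v30, v6)
  ref <- phantom_ref("chest", 128)
  dims <- dim(ref$pixels)
  noise <- display_from_matrix(
    ctfriqa:::with_seed(77, matrix(pmin(pmax(round(rnorm(prod(dims), 128, 50)),
                                             0), 255), dims[1], dims[2])))
  noise$source_id <- ref$source_id
  expect_lt(as.numeric(vif(image_pair(ref, noise, distortion_spec(30, 0)))),
            0.1)
  # pixel-domain variant agrees qualitatively
  expect_equal(as.numeric(vif(identical_pair(), domain = "pixel")), 1,
               tolerance = 1e-6)
})

test_that("NQM caps on identical images and decreases with noise", {
  n0 <- nqm(identical_pair())
  expect_identical(as.numeric(n0), 100)
  expect_true(attr(n0, "capped"))
  vals <- vapply(c(6, 14, 30), function(sn)
    as.numeric(nqm(noisy_pair(sn, seed = ctfriqa:::child_seed(3, sn)))),
    numeric(1))
  expect_true(all(diff(vals) < 0))
  # non-square shapes are accepted as-is
  x <- random_display(64, seed = 20)
  xr <- x; xr$pixels <- x$pixels[1:48, ]
  yr <- xr; yr$pixels[5, 5] <- yr$pixels[5, 5] + 40L
  expect_true(is.finite(as.numeric(nqm(image_pair(xr, yr,
                                                  distortion_spec(1, 0))))))
})

test_that("VSNR caps for imperceptible distortion and tracks noise", {
  v0 <- vsnr(identical_pair())
  expect_identical(as.numeric(v0), 100)
  expect_true(attr(v0, "capped"))
  # one-pixel +/-1 perturbation on a 256x256 flat field is below threshold
  a <- display_from_matrix(matrix(128L, 256, 256))
  b <- a; b$pixels[100, 100] <- 129L
  v1 <- vsnr(make_pair(a, b))
  expect_true(attr(v1, "capped"))
  vals <- vapply(c(6, 14, 30), function(sn)
    as.numeric(vsnr(noisy_pair(sn, seed = ctfriqa:::child_seed(4, sn)))),
    numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_false(any(vapply(c(6, 14, 30), function(sn)
    attr(vsnr(noisy_pair(sn, seed = sn)), "capped"), logical(1))))
})

test_that("compute_all yields complete, deterministic, finite vectors", {
  ref <- phantom_ref("abdomen", 96)
  pairs <- generate_grid(list(ref), noise_levels = c(9, 21),
                         blur_levels = c(1.4), base_seed = 6)
  tab1 <- score_pairs(pairs)
  tab2 <- score_pairs(pairs)
  expect_identical(tab1, tab2)
  expect_equal(nrow(tab1), 5)
  expect_false(anyNA(tab1[, METRIC_NAMES]))
  expect_true(all(vapply(tab1[, METRIC_NAMES], is.finite, logical(5))))
  expect_error(
    image_pair(phantom_ref("head", 96), phantom_ref("abdomen", 96),
               distortion_spec(6, 0)), "different sources|shape")
})
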