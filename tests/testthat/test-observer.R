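test_that("phantoms are deterministic and site-structured", {
  a <- make_phantom("chest", 96, seed = 12)
  b <- make_phantom("chest", 96, seed = 12)
  expect_identical(a$pixels, b$pixels)
  c_ <- make_phantom("chest", 96, seed = 13)
  expect_false(identical(a$pixels, c_$pixels))
  expect_error(make_phantom("head", 32), ">= 64")

  # lung fields darker than the body wall under the chest window
  disp <- window_to_display(a, site_window("chest"))
  masks <- attr(a, "masks")
  expect_lt(mean(disp$pixels[masks$lung]), mean(disp$pixels[masks$body_wall]))
})

test_that("body-mask bounding box matches the automatic crop", {
  for (site in c("head", "chest", "abdomen")) {
    ph <- make_phantom(site, 96, seed = 2)
    disp <- window_to_display(ph)
    cr <- crop_background(disp, threshold = 10, margin = 0)
    expect_identical(cr$crop_box, ctfriqa:::mask_bbox(attr(ph, "masks")$body))
  }
})

test_that("latent quality decays monotonically with shrinking decrements", {
  p <- observer_params()
  expect_equal(latent_quality(distortion_spec(0, 0), p), 100)
  q_noise <- latent_quality(list(sigma_noise = NOISE_LEVELS,
                                 sigma_blur = rep(0, 5)), p)
  q_blur <- latent_quality(list(sigma_noise = rep(0, 5),
                                sigma_blur = BLUR_LEVELS), p)
  # rate of decrease (decrement per unit sigma) declines along each grid
  for (gr in list(list(q = q_noise, s = NOISE_LEVELS),
                  list(q = q_blur, s = BLUR_LEVELS))) {
    drops <- -diff(c(100, gr$q))
    expect_true(all(drops > 0))          # strictly decreasing
    rates <- drops / diff(c(0, gr$s))
    expect_true(all(diff(rates) < 0))    # declining rate of decrease
  }
  expect_lt(latent_quality(distortion_spec(30, 0), p),
            latent_quality(distortion_spec(6, 0), p))
})

test_that("noiseless observers mark the exact latent quality", {
  grid <- default_study_grid()
  p <- observer_params(bias_sd = 0, mark_sd = 0)
  sheet <- simulate_marks(grid, p, seed = 3)
  q <- latent_quality(grid, p)
  for (o in unique(sheet$observer_id)) {
    sub <- sheet[sheet$observer_id == o, ]
    expect_equal(sub$mark_dist, q)
    expect_equal(sub$mark_ref, rep(p$ref_mean, nrow(grid)))
  }
})

test_that("mark sheets are reproducible and orders are per-observer", {
  grid <- default_study_grid()
  s1 <- simulate_marks(grid, seed = 9)
  s2 <- simulate_marks(grid, seed = 9)
  expect_identical(s1, s2)
  orders <- split(s1$order_index, s1$observer_id)
  for (o in orders) expect_setequal(o, seq_len(nrow(grid)))
  expect_false(identical(orders[[1]], orders[[2]]))
  expect_true(all(s1$mark_dist >= 0 & s1$mark_dist <= 100))
})

test_that("panel means concentrate around the latent quality", {
  grid <- default_study_grid()
  p <- observer_params(bias_sd = 0)
  sheet <- simulate_marks(grid, p, seed = 5)
  q <- latent_quality(grid, p)
  means <- tapply(sheet$mark_dist, sheet$pair_id, mean)[grid$pair_id]
  # CLT: mean over 210 pairs of panel-mean errors ~ mark_sd / sqrt(6 * 210)
  expect_lt(mean(abs(unname(means) - q)),  3 * p$mark_sd / sqrt(6))
  expect_lt(abs(mean(unname(means) - q)), 4 * p$mark_sd / sqrt(6 * nrow(grid)))
})

test_that("calibration hits the target agreement and is monotone", {
  p <- observer_params()
  grid <- default_study_grid()
  one_icc <- function(sd, r) {
    p2 <- p; p2$mark_sd <- sd
    icc_2_1(subjective_ratings(simulate_marks(grid, p2,
                                              seed = ctfriqa:::child_seed(7, r, sd)),
                               "difference"))$icc
  }
  # larger mark noise -> lower agreement (valid bisection bracket)
  lo <- mean(vapply(1:5, function(r) one_icc(3, r), numeric(1)))
  hi <- mean(vapply(1:5, function(r) one_icc(12, r), numeric(1)))
  expect_gt(lo, hi)

  cal <- calibrate_mark_noise(0.68, p, n_reps = 10, seed = 21)
  expect_gt(cal$mark_sd, 0)
  expect_lt(abs(cal$achieved_icc - 0.68), 0.031)

  perfect <- calibrate_mark_noise(1.0, observer_params(bias_sd = 0),
                                  n_reps = 3, seed = 4)
  expect_equal(perfect$mark_sd, 0)
  expect_equal(perfect$achieved_icc, 1)

  expect_error(
    calibrate_mark_noise(1.0, observer_params(bias_sd = 12), n_reps = 3,
                         seed = 4, ratings = "raw"),
    "unattainable")
})

test_that("latent-model parameters are recoverable from panel means", {
  grid <- default_study_grid()
  truth <- observer_params(bias_sd = 0, mark_sd = 5)
  sheet <- simulate_marks(grid, truth, seed = 31)
  means <- tapply(sheet$mark_dist, sheet$pair_id, mean)
  dat <- data.frame(q = unname(means[grid$pair_id]),
                    sn = grid$sigma_noise, sb = grid$sigma_blur)
  fit <- nls(q ~ fl + (100 - fl) * exp(-(sn / tn + sb / tb)), data = dat,
             start = list(fl = 25, tn = 10, tb = 1))
  est <- coef(fit)
  expect_lt(abs(est["tn"] - truth$tau_noise) / truth$tau_noise, 0.15)
  expect_lt(abs(est["tb"] - truth$tau_blur) / truth$tau_blur, 0.15)
})
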