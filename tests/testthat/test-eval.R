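fivepl <- function(Y, b) b[1] * (0.5 - 1 / (1 + exp(b[2] * (Y - b[3])))) +
  b[4] * Y + b[5]

test_that("5PL fit recovers a noiseless logistic curve", {
  Y <- seq(0, 30, length.out = 60)
  truth <- c(55, 0.4, 15, 0.5, 50)
  X <- fivepl(Y, truth)
  fit <- fit_5pl(Y, X)
  expect_lt(rmse(X, fit$fitted), 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$sse, sum(fit$residuals^2))
})

test_that("the logistic term vanishes at beta2 = 0, leaving a linear model", {
  Y <- seq(1, 20)
  X <- fivepl(Y, c(100, 0, 5, 2, 3))   # beta2 = 0 -> X = 2 Y + 3 exactly
  expect_equal(X, 2 * Y + 3)
  fit <- fit_5pl(Y, X)
  expect_lt(rmse(X, fit$fitted), 1e-8)
})

test_that("regression never hurts the linear correlation (nesting)", {
  for (seed in 1:4) {
    dat <- ctfriqa:::with_seed(seed, {
      Y <- runif(60, 0, 40)
      list(Y = Y, X = 90 - 1.8 * Y + rnorm(60, 0, 6))
    })
    fit <- fit_5pl(dat$Y, dat$X)
    expect_gte(plcc(dat$X, fit$fitted), abs(plcc(dat$X, dat$Y)) - 1e-9)
  }
})

test_that("degenerate 5PL inputs are flagged or rejected", {
  expect_error(fit_5pl(1:5, 1:5), "at least 8")
  fit <- fit_5pl(rep(3, 10), ctfriqa:::with_seed(2, rnorm(10, 50)))
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_error(fit_5pl(c(1:9, NA), 1:10), "non-finite")
})

test_that("PLCC matches affine relations and the direct-formula oracle", {
  x <- ctfriqa:::with_seed(5, rnorm(50, 10, 3))
  expect_equal(plcc(x, 2 * x + 1), 1)
  expect_equal(plcc(x, -x), -1)
  y <- ctfriqa:::with_seed(6, rnorm(50))
  expect_equal(plcc(x, y), cor(x, y), tolerance = 1e-12)
  expect_error(plcc(x, rep(1, 50)), "constant")
  expect_error(plcc(1:3, 1:4), "unequal")
})

test_that("SROCC is invariant to monotone transforms and handles ties", {
  x <- ctfriqa:::with_seed(7, runif(40, 0, 100))
  expect_equal(srocc(x, exp(x / 20)), 1)
  expect_equal(srocc(x, -x^3), -1)
  expect_equal(srocc(sort(x), rev(sort(x))), -1)
  # tie-free data: classical d^2 closed form equals rank-Pearson
  y <- ctfriqa:::with_seed(8, rnorm(40))
  d <- rank(x) - rank(y)
  n <- length(x)
  expect_equal(srocc(x, y), 1 - 6 * sum(d^2) / (n * (n^2 - 1)),
               tolerance = 1e-12)
  # capped scores produce ties yet SROCC stays defined
  y2 <- pmin(y, quantile(y, 0.7))
  expect_true(is.finite(srocc(x, y2)))
})

test_that("SROCC agrees before and after a monotone 5PL correction", {
  dat <- ctfriqa:::with_seed(9, {
    Y <- runif(80, 0, 30)
    list(Y = Y, X = 30 + 70 * exp(-Y / 10) + rnorm(80, 0, 3))
  })
  fit <- fit_5pl(dat$Y, dat$X)
  yl <- predict_5pl(fit, dat$Y)
  curve <- predict_5pl(fit, sort(dat$Y))
  expect_true(all(diff(curve) < 0) || all(diff(curve) > 0))  # monotone fit
  expect_equal(abs(srocc(dat$X, yl)), abs(srocc(dat$X, dat$Y)),
               tolerance = 1e-9)
})

test_that("RMSE matches hand values and the fit identity", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  Y <- seq(0, 20, length.out = 30)
  X <- 80 - 2.5 * Y + ctfriqa:::with_seed(10, rnorm(30, 0, 4))
  fit <- fit_5pl(Y, X)
  expect_equal(rmse(X, fit$fitted)^2 * length(X), fit$sse, tolerance = 1e-9)
})

test_that("the residual F-test discriminates variances one-tailed at 5%", {
  res <- ctfriqa:::with_seed(3, list(a = rnorm(210, 0, 1), b = rnorm(210, 0, 10)))
  expect_identical(residual_f_test(res$a, res$b), "1")
  expect_identical(residual_f_test(res$b, res$a), "0")
  expect_identical(residual_f_test(res$a, res$a), "-")
  # swapping arguments maps 1 <-> 0 and fixes "-"
  c_ <- ctfriqa:::with_seed(4, rnorm(210, 0, 1.1))
  swap <- c("1" = "0", "-" = "-", "0" = "1")
  expect_identical(residual_f_test(c_, res$a),
                   unname(swap[residual_f_test(res$a, c_)]))
  expect_error(residual_f_test(rep(0, 20), rep(0, 20)), "degenerate")
  expect_error(residual_f_test(rnorm(5), rnorm(5)), "at least 8")
})

test_that("significance matrices satisfy the structural invariants", {
  resids <- ctfriqa:::with_seed(6, {
    gs <- c("noise", "blur")
    setNames(lapply(c(1, 4, 4.2), function(s)
      setNames(lapply(gs, function(g) rnorm(30, 0, s)), gs)),
      c("m1", "m2", "m3"))
  })
  m <- significance_matrix(resids)
  expect_identical(dim(m), c(3L, 3L))
  expect_true(all(diag(m) == "- -"))
  # antisymmetry per symbol position
  swap <- c("1" = "0", "-" = "-", "0" = "1")
  for (i in 1:3) for (j in 1:3) {
    a <- strsplit(m[i, j], " ")[[1]]
    b <- strsplit(m[j, i], " ")[[1]]
    expect_identical(unname(swap[a]), b)
  }
  single <- significance_matrix(list(only = list(all = rnorm(30))))
  expect_identical(unclass(single)[1, 1], "-")
  tied <- significance_matrix(list(a = list(g = res <- rnorm(30)),
                                   b = list(g = res)))
  expect_true(all(tied == "-"))
})

test_that("evaluate produces complete per-group summaries", {
  grid <- default_study_grid()
  q <- latent_quality(grid)
  recs <- ctfriqa:::with_seed(12, {
    grid$subjective <- q + rnorm(nrow(grid), 0, 3)
    # two synthetic 'metrics': a noisy monotone transform of Q and a weaker one
    grid$M1 <- 20 * log(q) + rnorm(nrow(grid), 0, 0.5)
    grid$M2 <- q^1.5 + rnorm(nrow(grid), 0, 120)
    grid
  })
  ev <- evaluate(recs, metrics = c("M1", "M2"))
  expect_equal(nrow(ev$summary), 6 * 2)  # all/noise/blur + 3 sites, 2 methods
  expect_false(anyNA(ev$summary$plcc))
  expect_setequal(names(ev$significance), c("all", "distortion", "site"))
  expect_identical(attr(ev$significance$site, "subgroups"),
                   c("head", "chest", "abdomen"))
  # noise-only subgroup size = references x noise levels
  expect_equal(unique(ev$summary$n[ev$summary$group == "noise"]), 30)
  expect_gt(min(ev$summary$srocc[ev$summary$method == "M1"]), 0.85)
  # a subgroup below the minimum size is skipped with a warning
  tiny <- recs[recs$sigma_blur == 0 & recs$sigma_noise > 0, ][1:20, ]
  w <- capture_warnings(ev2 <- evaluate(tiny, metrics = "M1"))
  expect_true(any(grepl("skipped", w)))
  expect_true(any(is.na(ev2$summary$plcc)))
})
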