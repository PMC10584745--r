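# Performance-evaluation harness: five-parameter logistic nonlinearity
# correction, PLCC / SROCC / RMSE, one-tailed residual F-tests and
# pairwise significance matrices.

# The 5PL regression function mapping a raw objective score Y onto the
# subjective scale. Written with plogis for numerical stability:
# b1 * (1/2 - 1/(1 + exp(b2 (Y - b3)))) == b1 * (plogis(b2 (Y - b3)) - 1/2).
fivepl_fun <- function(Y, b) {
  b[1] * (stats::plogis(b[2] * (Y - b[3])) - 0.5) + b[4] * Y + b[5]
}

#' Fit the five-parameter logistic regression
#'
#' Least-squares fit of
#' `Y_L = b1 (1/2 - 1/(1 + exp(b2 (Y - b3)))) + b4 Y + b5`
#' minimizing `sum((Y_L - X)^2)`. Initialization: `b3 = median(Y)`,
#' `b1 = range(X) * sign(cor(X, Y))`, `b2 = 2 / sd(Y)`, `b4 = 0`,
#' `b5 = mean(X)`; a pure linear fit (`b1 = 0`) and, on failure, 16
#' jittered restarts serve as fallbacks, and the best (lowest SSE)
#' solution is kept, so the fit can never be worse than ordinary linear
#' regression.
#'
#' @param Y raw objective scores.
#' @param X subjective scores.
#' @return an object of class `fivepl_fit`: `beta` (b1..b5), `fitted`
#'   (Y_L), `residuals` (Y_L - X), `sse`, `converged`, `degenerate`.
#' @export
fit_5pl <- function(Y, X) {
  n <- length(Y)
  if (length(X) != n) stopf("X and Y must have equal length")
  if (n < 8) stopf("need at least 8 points to fit the 5PL model")
  if (any(!is.finite(Y)) || any(!is.finite(X)))
    stopf("non-finite values in regression inputs (cap metrics first)")
  if (stats::sd(Y) == 0) {
    b <- c(0, 0, 0, 0, mean(X))
    fitted <- rep(mean(X), n)
    return(structure(list(beta = b, fitted = fitted,
                          residuals = fitted - X,
                          sse = sum((fitted - X)^2),
                          converged = FALSE, degenerate = TRUE),
                     class = "fivepl_fit"))
  }
  dat <- data.frame(X = X, Y = Y)
  lmfit <- stats::lm(X ~ Y, data = dat)
  start_lin <- c(b1 = 0, b2 = 1 / stats::sd(Y), b3 = stats::median(Y),
                 b4 = unname(stats::coef(lmfit)[2]),
                 b5 = unname(stats::coef(lmfit)[1]))
  start_spec <- c(b1 = diff(range(X)) * sign(stats::cor(X, Y)),
                  b2 = 2 / stats::sd(Y), b3 = stats::median(Y),
                  b4 = 0, b5 = mean(X))
  try_fit <- function(st) {
    tryCatch({
      fit <- minpack.lm::nlsLM(
        X ~ b1 * (plogis(b2 * (Y - b3)) - 0.5) + b4 * Y + b5,
        data = dat, start = as.list(st),
        control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 5000,
                                             ftol = 1e-12, ptol = 1e-12))
      list(beta = stats::coef(fit), sse = sum(stats::resid(fit)^2),
           converged = fit$convInfo$isConv)
    }, error = function(e) NULL)
  }
  cands <- list(try_fit(start_spec), try_fit(start_lin))
  best <- Filter(Negate(is.null), cands)
  if (length(best) == 0 || min(vapply(best, `[[`, numeric(1), "sse")) >
      sum(stats::resid(lmfit)^2) + 1e-9) {
    # multi-start jitter fallback
    jit <- with_seed(1734, lapply(1:16, function(i)
      start_spec * stats::runif(5, 0.5, 1.5) + stats::rnorm(5, 0, 1e-3)))
    cands <- c(cands, lapply(jit, try_fit))
    best <- Filter(Negate(is.null), cands)
  }
  # linear regression is always an admissible solution of the nested model
  best <- c(best, list(list(
    beta = c(b1 = 0, b2 = 0, b3 = 0,
             b4 = unname(stats::coef(lmfit)[2]),
             b5 = unname(stats::coef(lmfit)[1])),
    sse = sum(stats::resid(lmfit)^2), converged = TRUE)))
  sses <- vapply(best, `[[`, numeric(1), "sse")
  top <- best[[which.min(sses)]]
  fitted <- fivepl_fun(Y, unname(top$beta))
  structure(list(beta = stats::setNames(unname(top$beta),
                                        paste0("b", 1:5)),
                 fitted = fitted, residuals = fitted - X,
                 sse = sum((fitted - X)^2),
                 converged = isTRUE(top$converged), degenerate = FALSE),
            class = "fivepl_fit")
}

#' Predict regressed scores from a 5PL fit
#' @param fit a `fivepl_fit`.
#' @param Y raw objective scores.
#' @return regressed scores `Y_L`.
#' @export
predict_5pl <- function(fit, Y) fivepl_fun(Y, unname(fit$beta))

#' Pearson linear correlation coefficient
#'
#' Computed from centered sums: `sum((X - mean)(Y - mean)) /
#' (sqrt(sum((X - mean)^2)) sqrt(sum((Y - mean)^2)))`.
#'
#' @param x,y equal-length numeric vectors, both non-constant, `n >= 3`.
#' @return correlation in `[-1, 1]`.
#' @export
plcc <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stopf("unequal lengths")
  if (n < 3) stopf("need at least 3 points")
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) stopf("correlation undefined for constant input")
  sum(dx * dy) / (sx * sy)
}

#' Spearman rank-order correlation coefficient
#'
#' Pearson correlation of mid-ranks, which equals the classical
#' `1 - 6 sum(d_i^2) / (n (n^2 - 1))` form whenever there are no ties and
#' remains well defined (tie-corrected) when capped metrics produce ties.
#'
#' @inheritParams plcc
#' @return rank correlation in `[-1, 1]`.
#' @export
srocc <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  plcc(rx, ry)
}

#' Root-mean-square error
#'
#' `sqrt(sum((y - x)^2) / n)`.
#'
#' @param x subjective scores.
#' @param y regressed objective scores.
#' @return RMSE (>= 0).
#' @export
rmse <- function(x, y) {
  if (length(y) != length(x)) stopf("unequal lengths")
  sqrt(mean((y - x)^2))
}

#' One-tailed residual F-test between two methods
#'
#' Tests the null that the two residual vectors have the same variance
#' with `F = var(a) / var(b)` on `(n - 1, n - 1)` degrees of freedom
#' (mean-centered sample variances). Returns `"1"` if method a's residual
#' variance is significantly smaller (a better), `"0"` if significantly
#' larger, `"-"` otherwise, at one-tailed level `alpha`.
#'
#' @param res_a,res_b equal-length residual vectors (`n >= 8`).
#' @param alpha one-tailed significance level (default 0.05).
#' @return a single character: `"1"`, `"-"` or `"0"`.
#' @export
residual_f_test <- function(res_a, res_b, alpha = 0.05) {
  n <- length(res_a)
  if (length(res_b) != n) stopf("unequal residual lengths")
  if (n < 8) stopf("need at least 8 residuals")
  va <- stats::var(res_a); vb <- stats::var(res_b)
  if (va == 0 && vb == 0) stopf("degenerate: both residual variances are zero")
  f <- va / vb
  p_smaller <- stats::pf(f, n - 1, n - 1)
  if (p_smaller < alpha) "1"
  else if (p_smaller > 1 - alpha) "0"
  else "-"
}

#' Pairwise significance matrix with per-subgroup codewords
#'
#' For every ordered method pair and every subgroup, runs
#' [residual_f_test()] on the subgroup residuals; the cell codeword
#' concatenates one symbol per subgroup in the declared order, separated
#' by spaces when there is more than one subgroup. Diagonal cells are all
#' `"-"`.
#'
#' @param residuals named list: per method, a named list of subgroups,
#'   each an equal-length residual vector. All methods must share the same
#'   subgroup names.
#' @param alpha one-tailed significance level.
#' @return a character matrix of class `significance_matrix` with
#'   attributes `subgroups` and `alpha`.
#' @export
significance_matrix <- function(residuals, alpha = 0.05) {
  methods <- names(residuals)
  stopifnot(length(methods) >= 1)
  subgroups <- names(residuals[[1]])
  sep <- if (length(subgroups) > 1) " " else ""
  out <- matrix("", length(methods), length(methods),
                dimnames = list(methods, methods))
  for (i in seq_along(methods)) for (j in seq_along(methods)) {
    syms <- if (i == j) rep("-", length(subgroups))
            else vapply(subgroups, function(s)
              residual_f_test(residuals[[i]][[s]], residuals[[j]][[s]],
                              alpha), character(1))
    out[i, j] <- paste(syms, collapse = sep)
  }
  structure(out, subgroups = subgroups, alpha = alpha,
            class = c("significance_matrix", "matrix"))
}

#' Evaluate FR-IQA performance against subjective scores
#'
#' For every metric and subgroup (all images; noise-only; blur-only; one
#' per site), fits the 5PL nonlinearity per subgroup, then computes PLCC
#' and RMSE on the regressed scores and SROCC on the raw scores, plus the
#' three significance matrices of pairwise one-tailed residual F-tests
#' (overall; `[noise, blur]` codewords; `[head, chest, abdomen]`
#' codewords).
#'
#' @param records data frame with columns `pair_id`, `site`,
#'   `sigma_noise`, `sigma_blur`, `subjective`, and one column per metric
#'   in `metrics`.
#' @param metrics metric column names (default [METRIC_NAMES]).
#' @param alpha F-test significance level (default 0.05).
#' @return list of class `iqa_evaluation`: `summary` (long data frame of
#'   group x method PLCC/SROCC/RMSE), `significance` (list `all`,
#'   `distortion`, `site` of [significance_matrix()]s), `fits`.
#' @export
evaluate <- function(records, metrics = METRIC_NAMES, alpha = 0.05) {
  stopifnot(all(c("site", "sigma_noise", "sigma_blur", "subjective")
                %in% names(records)),
            all(metrics %in% names(records)))
  groups <- list(
    all = rep(TRUE, nrow(records)),
    noise = records$sigma_blur == 0 & records$sigma_noise > 0,
    blur = records$sigma_noise == 0 & records$sigma_blur > 0)
  for (s in intersect(CT_SITES, unique(records$site)))
    groups[[s]] <- records$site == s
  rows <- list(); fits <- list()
  for (g in names(groups)) {
    sub <- records[groups[[g]], , drop = FALSE]
    if (nrow(sub) < 8) {
      warning(sprintf("subgroup '%s' has n = %d < 8; skipped", g, nrow(sub)),
              call. = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, method = metrics, n = nrow(sub), plcc = NA_real_,
        srocc = NA_real_, rmse = NA_real_, converged = NA,
        stringsAsFactors = FALSE)
      next
    }
    for (mth in metrics) {
      fit <- fit_5pl(sub[[mth]], sub$subjective)
      fits[[g]][[mth]] <- fit
      rows[[length(rows) + 1]] <- data.frame(
        group = g, method = mth, n = nrow(sub),
        plcc = plcc(sub$subjective, fit$fitted),
        srocc = srocc(sub$subjective, sub[[mth]]),
        rmse = rmse(sub$subjective, fit$fitted),
        converged = fit$converged, stringsAsFactors = FALSE)
    }
  }
  res_of <- function(gs) {
    stats::setNames(lapply(metrics, function(mth)
      stats::setNames(lapply(gs, function(g) fits[[g]][[mth]]$residuals), gs)),
      metrics)
  }
  sig <- list()
  if (!is.null(fits$all))
    sig$all <- significance_matrix(res_of("all"), alpha)
  if (!is.null(fits$noise) && !is.null(fits$blur))
    sig$distortion <- significance_matrix(res_of(c("noise", "blur")), alpha)
  sites_present <- intersect(CT_SITES, names(fits))
  if (length(sites_present) >= 1)
    sig$site <- significance_matrix(res_of(sites_present), alpha)
  structure(list(summary = do.call(rbind, rows), significance = sig,
                 fits = fits),
            class = "iqa_evaluation")
}
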