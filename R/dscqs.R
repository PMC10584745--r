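# DSCQS scoring and inter-rater agreement.

#' DSCQS and subjective scores from a mark sheet
#'
#' Per pair and observer, the quality difference is
#' `mark_ref - mark_dist`; the DSCQS score is the mean difference over
#' observers and the subjective score is `X = 100 - DSCQS` (no clipping).
#'
#' @param sheet a mark sheet (long data frame with `pair_id`,
#'   `observer_id`, `mark_ref`, `mark_dist`); must be complete.
#' @return data frame (`pair_id`, `dscqs`, `subjective`, `n_observers`)
#'   with the per-observer difference matrix (pairs x observers) attached
#'   as attribute `differences`.
#' @export
dscqs_scores <- function(sheet) {
  stopifnot(all(c("pair_id", "observer_id", "mark_ref", "mark_dist")
                %in% names(sheet)))
  pairs <- unique(sheet$pair_id)
  obs <- sort(unique(sheet$observer_id))
  if (length(obs) < 2) stopf("need at least 2 observers")
  counts <- table(sheet$pair_id, sheet$observer_id)
  if (any(counts != 1)) {
    bad <- rownames(counts)[rowSums(counts != 1) > 0]
    stopf("mark sheet incomplete for pair(s): %s",
          paste(utils::head(bad, 10), collapse = ", "))
  }
  diffs <- matrix(NA_real_, length(pairs), length(obs),
                  dimnames = list(pairs, obs))
  idx <- cbind(match(sheet$pair_id, pairs), match(sheet$observer_id, obs))
  diffs[idx] <- sheet$mark_ref - sheet$mark_dist
  dscqs <- rowMeans(diffs)
  out <- data.frame(pair_id = pairs, dscqs = dscqs,
                    subjective = 100 - dscqs,
                    n_observers = length(obs),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "differences") <- diffs
  out
}

#' Ratings matrix for agreement analysis
#'
#' `"difference"` (default) returns per-observer subjective scores,
#' `100 - (mark_ref - mark_dist)`, so agreement concerns the perceived
#' quality difference; `"raw"` returns the raw distorted-image marks.
#'
#' @param sheet a complete mark sheet.
#' @param type `"difference"` or `"raw"`.
#' @return numeric items x observers matrix.
#' @export
subjective_ratings <- function(sheet, type = c("difference", "raw")) {
  type <- match.arg(type)
  pairs <- unique(sheet$pair_id)
  obs <- sort(unique(sheet$observer_id))
  m <- matrix(NA_real_, length(pairs), length(obs),
              dimnames = list(pairs, obs))
  idx <- cbind(match(sheet$pair_id, pairs), match(sheet$observer_id, obs))
  m[idx] <- switch(type,
    difference = 100 - (sheet$mark_ref - sheet$mark_dist),
    raw = sheet$mark_dist)
  if (anyNA(m)) stopf("mark sheet incomplete")
  m
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measure:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` from the two-way
#' ANOVA mean squares of an items x observers matrix, with the
#' F-distribution based two-sided 95% confidence interval (McGraw-Wong).
#' `type = "consistency"` gives ICC(3,1) instead.
#'
#' @param ratings numeric matrix, items in rows, observers in columns; at
#'   least 2 x 2, no missing values.
#' @param conf_level confidence level (default 0.95).
#' @param type `"agreement"` (default, ICC(2,1)) or `"consistency"`
#'   (ICC(3,1)).
#' @return list of class `icc_result`: `icc`, `ci_low`, `ci_high`, and
#'   variance components `var_items`, `var_observers`, `var_residual`.
#' @export
icc_2_1 <- function(ratings, conf_level = 0.95,
                    type = c("agreement", "consistency")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stopf("need at least 2 items and 2 observers")
  if (anyNA(ratings)) stopf("ratings matrix contains missing values")
  g <- mean(ratings)
  if (sum((ratings - g)^2) == 0)
    stopf("degenerate ratings matrix: no variance")
  ri <- rowMeans(ratings); cj <- colMeans(ratings)
  ssr <- k * sum((ri - g)^2)
  ssc <- n * sum((cj - g)^2)
  sst <- sum((ratings - g)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  alpha <- 1 - conf_level
  if (type == "consistency") {
    fl <- (msr / mse) / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- (msr / mse) * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else if (1 - icc < 1e-12 || mse == 0) {
    ci <- c(icc, 1)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    ci <- c(
      n * (msr - f_l * mse) /
        (f_l * (k * msc + (k * n - k - n) * mse) + n * msr),
      n * (f_u * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_u * msr))
  }
  structure(list(icc = icc, ci_low = min(ci[1], icc), ci_high = max(ci[2], icc),
                 var_items = (msr - mse) / k,
                 var_observers = max((msc - mse) / n, 0),
                 var_residual = mse,
                 msr = msr, msc = msc, mse = mse,
                 n_items = n, n_observers = k, type = type),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s, single measure) = %.3f [%.3f, %.3f]\n",
              if (x$type == "agreement") "2,1" else "3,1",
              x$icc, x$ci_low, x$ci_high))
  invisible(x)
}
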