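# Metric score vectors: all nine FR-IQA methods on one pair.

#' Metric names in canonical order
#' @export
METRIC_NAMES <- c("PSNR", "SSIM", "FSIM", "IFC", "VIF",
                  "NQM", "VSNR", "MSSSIM", "IWSSIM")

#' Compute all nine FR-IQA scores for an image pair
#'
#' Runs PSNR, SSIM, FSIM, IFC, VIF, NQM, VSNR, MS-SSIM and IW-SSIM with
#' their default parameters. A failure in one metric is recorded for that
#' metric (score `NA`, message in `errors`) and does not abort the rest.
#'
#' @param pair an [image_pair()].
#' @return an object of class `metric_score_vector`: list with `scores`
#'   (named numeric), `capped` (named logical) and `errors` (named
#'   character, failures only).
#' @export
compute_all <- function(pair) {
  fns <- list(PSNR = psnr, SSIM = ssim, FSIM = fsim, IFC = ifc, VIF = vif,
              NQM = nqm, VSNR = vsnr, MSSSIM = ms_ssim, IWSSIM = iw_ssim)
  scores <- stats::setNames(rep(NA_real_, length(METRIC_NAMES)), METRIC_NAMES)
  capped <- stats::setNames(rep(FALSE, length(METRIC_NAMES)), METRIC_NAMES)
  errors <- character(0)
  for (nm in METRIC_NAMES) {
    res <- tryCatch(fns[[nm]](pair), error = function(e) e)
    if (inherits(res, "error")) {
      errors[nm] <- conditionMessage(res)
    } else {
      scores[nm] <- as.numeric(res)
      capped[nm] <- isTRUE(attr(res, "capped"))
    }
  }
  structure(list(scores = scores, capped = capped, errors = errors),
            class = "metric_score_vector")
}

#' @export
print.metric_score_vector <- function(x, ...) {
  cat("<metric_score_vector>\n")
  print(round(x$scores, 4))
  if (any(x$capped)) cat("capped:", names(x$capped)[x$capped], "\n")
  if (length(x$errors)) cat("errors:", names(x$errors), "\n")
  invisible(x)
}

#' Score a list of image pairs
#'
#' @param pairs list of [image_pair()]s.
#' @return data frame: manifest columns plus one column per metric and one
#'   logical `<metric>_capped` column per capped metric.
#' @export
score_pairs <- function(pairs) {
  man <- pair_manifest(pairs)
  vecs <- lapply(pairs, compute_all)
  sc <- do.call(rbind, lapply(vecs, function(v) as.data.frame(as.list(v$scores))))
  cp <- do.call(rbind, lapply(vecs, function(v) {
    d <- as.data.frame(as.list(v$capped))
    names(d) <- paste0(names(v$capped), "_capped")
    d
  }))
  cbind(man, sc, cp)
}
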