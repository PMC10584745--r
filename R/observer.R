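# Simulated DSCQS observer panel: a latent quality model with exponential
# decay to a plateau, between-observer bias and within-observer mark
# noise, plus a calibration routine that targets a desired inter-rater
# agreement (ICC(2,1)).

#' Observer model parameters
#'
#' The latent quality of a distorted image decays exponentially from 100
#' toward `floor` with characteristic scales `tau_noise` (gray levels) and
#' `tau_blur` (pixels). Each observer carries a session-constant bias
#' (`bias_sd`) applied to both marks of a pair, and each individual mark
#' receives independent noise (`mark_sd`). The default `mark_sd` is
#' calibrated so a six-observer panel on the default study grid reproduces
#' an ICC(2,1) of about 0.68.
#'
#' @param floor subjective-score plateau for extreme distortion (default 30).
#' @param tau_noise noise decay scale in gray levels (default 12).
#' @param tau_blur blur decay scale in pixels (default 1.2).
#' @param ref_mean mean mark assigned to reference images (default 85).
#' @param bias_sd SD of the between-observer bias (default 5).
#' @param mark_sd SD of the within-observer mark noise (default 5.7).
#' @param n_observers panel size (default 6, minimum 2).
#' @return an object of class `observer_params`.
#' @export
observer_params <- function(floor = 30, tau_noise = 12, tau_blur = 1.2,
                            ref_mean = 85, bias_sd = 5, mark_sd = 5.7,
                            n_observers = 6) {
  if (floor < 0 || floor >= 100) stopf("floor must lie in [0, 100)")
  if (bias_sd < 0 || mark_sd < 0) stopf("SDs must be >= 0")
  if (n_observers < 2) stopf("need at least 2 observers")
  structure(list(floor = floor, tau_noise = tau_noise, tau_blur = tau_blur,
                 ref_mean = ref_mean, bias_sd = bias_sd, mark_sd = mark_sd,
                 n_observers = as.integer(n_observers)),
            class = "observer_params")
}

#' Latent subjective quality of a distortion condition
#'
#' `Q = floor + (100 - floor) * exp(-(sigma_noise / tau_noise +
#' sigma_blur / tau_blur))`: strictly decreasing in each sigma with a
#' declining rate of decrease, and `Q(0, 0) = 100`.
#'
#' @param spec a [distortion_spec()], or anything with `sigma_noise` and
#'   `sigma_blur` fields; vectors are accepted.
#' @param params an [observer_params()].
#' @return latent quality in `[floor, 100]`.
#' @export
latent_quality <- function(spec, params = observer_params()) {
  params$floor + (100 - params$floor) *
    exp(-(spec$sigma_noise / params$tau_noise +
          spec$sigma_blur / params$tau_blur))
}

# Accept either a list of image_pairs or a manifest-like data frame.
as_pair_table <- function(pairs) {
  if (is.data.frame(pairs)) {
    stopifnot(all(c("pair_id", "sigma_noise", "sigma_blur") %in% names(pairs)))
    return(pairs)
  }
  pair_manifest(pairs)
}

#' Simulate a DSCQS mark sheet
#'
#' Every observer marks both images of every pair on the continuous 0-100
#' scale: the distorted mark is the latent quality plus the observer's
#' bias and mark noise, the reference mark is `ref_mean` plus the same
#' bias and independent mark noise; both are clipped to `[0, 100]`. The
#' presentation order is randomized independently per observer and
#' recorded in `order_index`. Deterministic given `seed`.
#'
#' @param pairs list of [image_pair()]s or a manifest data frame with
#'   `pair_id`, `sigma_noise`, `sigma_blur`.
#' @param params an [observer_params()].
#' @param seed integer seed.
#' @return long-format data frame (`pair_id`, `observer_id`, `mark_ref`,
#'   `mark_dist`, `order_index`) of class `mark_sheet`.
#' @export
simulate_marks <- function(pairs, params = observer_params(), seed = 1L) {
  tab <- as_pair_table(pairs)
  if (nrow(tab) == 0) stopf("no pairs to mark")
  n <- nrow(tab); k <- params$n_observers
  q <- latent_quality(tab, params)
  with_seed(seed, {
    bias <- stats::rnorm(k, 0, params$bias_sd)
    sheets <- lapply(seq_len(k), function(o) {
      eps_d <- stats::rnorm(n, 0, params$mark_sd)
      eps_r <- stats::rnorm(n, 0, params$mark_sd)
      ord <- sample.int(n)
      data.frame(
        pair_id = tab$pair_id,
        observer_id = sprintf("obs%02d", o),
        mark_ref = clip(params$ref_mean + bias[o] + eps_r, 0, 100),
        mark_dist = clip(q + bias[o] + eps_d, 0, 100),
        order_index = order(ord),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, sheets)
    class(out) <- c("mark_sheet", "data.frame")
    out
  })
}

#' Calibrate the mark noise to a target inter-rater agreement
#'
#' Bisection on `mark_sd` so that the mean simulated ICC(2,1) over
#' `n_reps` replicate studies falls within `tol` of `target_icc`.
#' Agreement is computed on the per-observer subjective scores
#' (`100 - (mark_ref - mark_dist)`) by default, or on raw distorted marks
#' with `ratings = "raw"`.
#'
#' @param target_icc target ICC(2,1) in `(0, 1]`.
#' @param params an [observer_params()] (its `mark_sd` is ignored).
#' @param grid manifest data frame of distortion conditions; defaults to
#'   the full six-reference study grid.
#' @param n_reps replicate studies averaged per evaluation (default 20).
#' @param seed integer seed.
#' @param tol calibration tolerance on the ICC scale (default 0.03).
#' @param ratings `"difference"` (default) or `"raw"`, see [subjective_ratings()].
#' @return list with `mark_sd` (calibrated SD) and `achieved_icc`.
#' @export
calibrate_mark_noise <- function(target_icc, params = observer_params(),
                                 grid = default_study_grid(), n_reps = 20,
                                 seed = 1L, tol = 0.03,
                                 ratings = c("difference", "raw")) {
  ratings <- match.arg(ratings)
  if (target_icc <= 0 || target_icc > 1) stopf("target ICC must lie in (0, 1]")
  mean_icc <- function(sd) {
    p <- params; p$mark_sd <- sd
    mean(vapply(seq_len(n_reps), function(r) {
      sheet <- simulate_marks(grid, p, seed = child_seed(seed, "rep", r, sd))
      icc_2_1(subjective_ratings(sheet, ratings))$icc
    }, numeric(1)))
  }
  icc0 <- mean_icc(0)
  if (icc0 < target_icc - tol)
    stopf("target ICC %.3f unattainable: even mark_sd = 0 yields %.3f",
          target_icc, icc0)
  if (abs(icc0 - target_icc) <= tol)
    return(list(mark_sd = 0, achieved_icc = icc0))
  lo <- 0; hi <- 4; icc_hi <- mean_icc(hi)
  while (icc_hi > target_icc && hi < 512) {
    hi <- hi * 2; icc_hi <- mean_icc(hi)
  }
  if (icc_hi > target_icc)
    stopf("target ICC %.3f unattainable within the searched mark_sd range",
          target_icc)
  achieved <- icc_hi; mid <- hi
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    achieved <- mean_icc(mid)
    if (abs(achieved - target_icc) <= tol) break
    if (achieved > target_icc) lo <- mid else hi <- mid
  }
  list(mark_sd = mid, achieved_icc = achieved)
}

#' Default six-reference study grid manifest
#'
#' Two phantoms per site crossed with the default noise/blur grid; 210
#' conditions.
#'
#' @param noise_levels,blur_levels distortion grids.
#' @return manifest data frame with `pair_id`, `source_id`, `site`,
#'   `sigma_noise`, `sigma_blur`.
#' @export
default_study_grid <- function(noise_levels = NOISE_LEVELS,
                               blur_levels = BLUR_LEVELS) {
  refs <- data.frame(
    source_id = paste0(rep(CT_SITES, each = 2), 1:2),
    site = rep(CT_SITES, each = 2), stringsAsFactors = FALSE)
  specs <- grid_specs(noise_levels, blur_levels)
  out <- merge(refs, specs, by = NULL)
  out$pair_id <- sprintf("%s_n%g_b%g", out$source_id,
                         out$sigma_noise, out$sigma_blur)
  out[, c("pair_id", "source_id", "site", "sigma_noise", "sigma_blur")]
}
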