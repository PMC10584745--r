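# End-to-end synthetic study orchestration: phantoms -> windowing/crop ->
# distortion grid -> metric scores -> simulated observers -> DSCQS ->
# performance evaluation, all reproducible from one config and base seed.

#' Study configuration
#'
#' All knobs of the end-to-end synthetic study. The single `base_seed`
#' fans out to per-stage child seeds (phantoms, distortions, observers)
#' via a deterministic counter scheme, so each stage is independently
#' reproducible.
#'
#' @param references data frame with `id` and `site` columns; defaults to
#'   two phantoms per site (the six-reference design).
#' @param size phantom size in pixels (default 256, the package's default
#'   study scale; clinical slices are 512).
#' @param noise_levels,blur_levels distortion grids.
#' @param observer an [observer_params()].
#' @param crop_threshold,crop_margin background-crop parameters.
#' @param distortion_order `"blur_first"` or `"noise_first"`.
#' @param base_seed integer base seed.
#' @param texture_scale phantom texture multiplier.
#' @return an object of class `study_config` (a named list).
#' @export
study_config <- function(references = NULL, size = 256,
                         noise_levels = NOISE_LEVELS,
                         blur_levels = BLUR_LEVELS,
                         observer = observer_params(),
                         crop_threshold = 10, crop_margin = 2,
                         distortion_order = "blur_first",
                         base_seed = 1L, texture_scale = 1) {
  if (is.null(references)) {
    references <- data.frame(
      id = paste0(rep(CT_SITES, each = 2), 1:2),
      site = rep(CT_SITES, each = 2), stringsAsFactors = FALSE)
  }
  structure(list(references = references, size = size,
                 noise_levels = noise_levels, blur_levels = blur_levels,
                 observer = observer, crop_threshold = crop_threshold,
                 crop_margin = crop_margin,
                 distortion_order = distortion_order,
                 base_seed = as.integer(base_seed),
                 texture_scale = texture_scale),
            class = "study_config")
}

#' Write / read a study configuration as YAML
#'
#' Round-trips losslessly through [yaml::write_yaml()].
#'
#' @param config a [study_config()].
#' @param path YAML file path.
#' @return `path` (write) or the `study_config` (read).
#' @export
write_study_config <- function(config, path) {
  plain <- unclass(config)
  plain$observer <- unclass(plain$observer)
  plain$references <- as.list(plain$references)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  plain <- yaml::read_yaml(path)
  study_config(
    references = data.frame(plain$references, stringsAsFactors = FALSE),
    size = plain$size, noise_levels = unlist(plain$noise_levels),
    blur_levels = unlist(plain$blur_levels),
    observer = do.call(observer_params, plain$observer),
    crop_threshold = plain$crop_threshold, crop_margin = plain$crop_margin,
    distortion_order = plain$distortion_order,
    base_seed = plain$base_seed, texture_scale = plain$texture_scale)
}

#' Run the full synthetic study
#'
#' Generates phantom references, windows and crops them, builds the
#' distortion grid, scores every pair with all nine metrics, simulates
#' the DSCQS observer panel, computes subjective scores and ICC(2,1),
#' and evaluates metric performance. With `out_dir` set, writes the
#' manifest, score/subjective tables, summaries, significance matrices,
#' ICC report and a run log; a `STATUS` sentinel file reads `INVALID`
#' while the run is incomplete and `OK` afterwards.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param write_images also write reference/distorted PNGs (default FALSE).
#' @param compute_metrics set FALSE to skip metric scoring (design-count
#'   and observer-only runs are much faster).
#' @return list of class `study_result`: `records` (one row per distorted
#'   image: spec, metric scores, subjective score), `evaluation` (when
#'   metrics were computed), `icc`, `sheet`, `pairs`, `config`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      write_images = FALSE, compute_metrics = TRUE) {
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines("INVALID", file.path(out_dir, "STATUS"))
  }
  bs <- config$base_seed
  refs <- vector("list", nrow(config$references))
  for (i in seq_len(nrow(config$references))) {
    id <- config$references$id[i]; site <- config$references$site[i]
    ph <- make_phantom(site, size = config$size,
                       seed = child_seed(bs, "phantom", id),
                       texture_scale = config$texture_scale, id = id)
    disp <- window_to_display(ph, site_window(site))
    refs[[i]] <- crop_background(disp, threshold = config$crop_threshold,
                                 margin = config$crop_margin)
    if (!is.null(out_dir) && write_images)
      write_raw_png(ph, file.path(out_dir, paste0(id, "_raw.png")))
  }
  pairs <- generate_grid(refs, config$noise_levels, config$blur_levels,
                         base_seed = child_seed(bs, "distort"),
                         order = config$distortion_order)
  man <- pair_manifest(pairs)
  man$site <- config$references$site[match(man$source_id,
                                           config$references$id)]
  sheet <- simulate_marks(man, config$observer,
                          seed = child_seed(bs, "observer"))
  subj <- dscqs_scores(sheet)
  icc <- icc_2_1(subjective_ratings(sheet, "difference"))
  records <- merge(man, subj[, c("pair_id", "dscqs", "subjective")],
                   by = "pair_id", sort = FALSE)
  evaluation <- NULL
  if (compute_metrics) {
    scored <- score_pairs(pairs)
    records <- merge(records,
                     scored[, c("pair_id", METRIC_NAMES,
                                paste0(METRIC_NAMES, "_capped"))],
                     by = "pair_id", sort = FALSE)
    evaluation <- evaluate(records)
  }
  records <- records[order(records$pair_id), , drop = FALSE]
  rownames(records) <- NULL
  result <- structure(list(records = records, evaluation = evaluation,
                           icc = icc, sheet = sheet, pairs = pairs,
                           config = config),
                      class = "study_result")
  if (!is.null(out_dir)) {
    write_tables(result, out_dir, write_images = write_images)
    writeLines("OK", file.path(out_dir, "STATUS"))
  }
  result
}

fmt6 <- function(x) {
  if (is.numeric(x)) signif(x, 6) else x
}

#' Write study result tables
#'
#' Emits `manifest.csv`, `marksheet.csv`, `subjective.csv`, `records.csv`
#' (full precision, round-trippable), `summary.csv` (6 significant
#' digits), one `significance_<scope>.csv` per codeword matrix,
#' `icc.json` and `runlog.json`. Subgroups that were skipped for
#' insufficient size appear in the summary with a `skipped` marker.
#'
#' @param result a `study_result`.
#' @param dir output directory.
#' @param write_images also dump distorted-image PNGs.
#' @return `dir`, invisibly.
#' @export
write_tables <- function(result, dir, write_images = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                          row.names = FALSE)
  man <- pair_manifest(result$pairs)
  wcsv(man, "manifest.csv")
  wcsv(result$sheet, "marksheet.csv")
  subj <- result$records[, intersect(c("pair_id", "sigma_noise", "sigma_blur",
                                       "site", "subjective", "dscqs"),
                                     names(result$records))]
  wcsv(subj, "subjective.csv")
  recs <- result$records
  num <- vapply(recs, is.numeric, logical(1))
  recs[num] <- lapply(recs[num], function(x) format(x, digits = 17,
                                                    scientific = FALSE,
                                                    trim = TRUE))
  wcsv(recs, "records.csv")
  if (!is.null(result$evaluation)) {
    summ <- result$evaluation$summary
    summ$status <- ifelse(is.na(summ$plcc), "skipped", "ok")
    for (cc in c("plcc", "srocc", "rmse")) summ[[cc]] <- fmt6(summ[[cc]])
    wcsv(summ, "summary.csv")
    for (nm in names(result$evaluation$significance)) {
      m <- result$evaluation$significance[[nm]]
      d <- as.data.frame(unclass(m), stringsAsFactors = FALSE)
      d <- cbind(method = rownames(m), d)
      wcsv(d, paste0("significance_", nm, ".csv"))
    }
  }
  icc <- result$icc
  jsonlite::write_json(
    list(icc = icc$icc, ci_low = icc$ci_low, ci_high = icc$ci_high,
         n_items = icc$n_items, n_observers = icc$n_observers),
    file.path(dir, "icc.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("ctfriqa")),
         r_version = R.version.string,
         base_seed = result$config$base_seed,
         size = result$config$size,
         n_references = nrow(result$config$references),
         n_pairs = length(result$pairs),
         timestamp = format(Sys.time(), tz = "UTC")),
    file.path(dir, "runlog.json"), auto_unbox = TRUE)
  if (write_images) {
    for (p in result$pairs) {
      id <- sprintf("%s_n%g_b%g.png", p$reference$source_id,
                    p$spec$sigma_noise, p$spec$sigma_blur)
      png::writePNG(p$distorted$pixels / 255, file.path(dir, id))
    }
  }
  invisible(dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d references, %d distorted pairs, ICC(2,1) = %.3f\n",
              nrow(x$config$references), length(x$pairs), x$icc$icc))
  if (!is.null(x$evaluation)) {
    s <- x$evaluation$summary
    cat("overall SROCC:\n")
    print(stats::setNames(round(s$srocc[s$group == "all"], 3),
                          s$method[s$group == "all"]))
  }
  invisible(x)
}
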