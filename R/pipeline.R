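#' Pipeline configuration
#'
#' Validated bundle of the tunable processing parameters shared by the two
#' pipelines. `st_bins` is fixed at 256 (the histogram convention of the
#' Shanbhag threshold) and is exposed only for the record.
#'
#' @param mhf_sigma_px Gaussian sigma of the Mexican-hat filter (px).
#' @param mhf_cutoff response cutoff of the ridge binarization.
#' @param min_filter_window minimum-filter window side (default 2).
#' @param connectivity component-count connectivity, 4 or 8.
#' @param ci_method Bland-Altman CI rule, `"normal"` or `"t"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mhf_sigma_px = 2, mhf_cutoff = 0,
                            min_filter_window = 2L, connectivity = 8L,
                            ci_method = c("normal", "t")) {
  ci_method <- match.arg(ci_method)
  if (!is_scalar_number(mhf_sigma_px) || mhf_sigma_px <= 0)
    stopf("`mhf_sigma_px` must be positive")
  if (min_filter_window < 1L) stopf("`min_filter_window` must be >= 1")
  if (!connectivity %in% c(4L, 8L)) stopf("`connectivity` must be 4 or 8")
  structure(list(mhf_sigma_px = mhf_sigma_px, mhf_cutoff = mhf_cutoff,
                 min_filter_window = as.integer(min_filter_window),
                 st_bins = 256L, connectivity = as.integer(connectivity),
                 ci_method = ci_method),
            class = "pipeline_config")
}

run_branch <- function(image, config, subject_id, binarize, faz_omitted = NA) {
  stages <- list()
  result <- tryCatch({
    stage <- "convert_to_16bit"
    img <- convert_to_16bit(image)
    stage <- "minimum_filter"
    img <- minimum_filter(img, config$min_filter_window)
    stage <- "binarize"
    bundle <- binarize(img)           # may include the FAZ cut (MHF branch)
    binary <- bundle$binary
    stage <- "skeletonize"
    skeleton <- skeletonize(binary)
    stage <- "sector_metrics"
    grid <- build_etdrs_grid(dim(image$pixels), image$fovea_center,
                             image$scale_mm_per_px, image$laterality)
    metrics <- sector_metrics(binary, skeleton, grid,
                              subject_id = subject_id)
    stage <- "quality"
    quality <- quality_report(binary, connectivity = config$connectivity)
    list(subject_id = subject_id, method = binary$method, binary = binary,
         skeleton = skeleton, grid = grid, metrics = metrics,
         quality = quality, faz_omitted = faz_omitted, error = NULL)
  }, error = function(e) {
    list(subject_id = subject_id, method = NA_character_, error = list(
      stage = stage, message = conditionMessage(e)))
  })
  result
}

#' Run the Mexican-hat pipeline on one image
#'
#' Executes, in order: 16-bit conversion, minimum filtering, manual FAZ
#' removal (cut), Mexican-hat ridge binarization, skeletonization, ETDRS
#' sector counting and metric computation, plus the per-image quality
#' report. A missing FAZ selection is tolerated as an empty cut and flagged
#' in the result (`faz_omitted = TRUE`). Stage failures are captured per
#' subject in `$error` with the failing stage's name.
#'
#' @param image an [en_face_angiogram()].
#' @param faz a [faz_selection()], or `NULL` to skip the cut.
#' @param config a [pipeline_config()].
#' @param subject_id identifier carried into the metrics.
#' @return A list (one pipeline branch) with `binary`, `skeleton`, `grid`,
#'   `metrics`, `quality`, `faz_omitted` and `error` (NULL on success).
#' @export
run_mhf_pipeline <- function(image, faz = NULL, config = pipeline_config(),
                             subject_id = NA) {
  stopifnot(inherits(image, "en_face_angiogram"),
            inherits(config, "pipeline_config"))
  run_branch(image, config, subject_id, faz_omitted = is.null(faz),
             binarize = function(img) {
               if (!is.null(faz)) img <- cut_faz(img, faz)
               list(binary = binarize_mhf(img, config$mhf_sigma_px,
                                          config$mhf_cutoff))
             })
}

#' Run the Shanbhag pipeline on one image
#'
#' Executes 16-bit conversion, minimum filtering, Shanbhag thresholding and
#' skeletonization, then sector metrics and the quality report. No FAZ input
#' is accepted: the avascular zone sits at background intensity and falls
#' below the threshold automatically.
#'
#' @inheritParams run_mhf_pipeline
#' @return As [run_mhf_pipeline()].
#' @export
run_st_pipeline <- function(image, config = pipeline_config(),
                            subject_id = NA) {
  stopifnot(inherits(image, "en_face_angiogram"),
            inherits(config, "pipeline_config"))
  run_branch(image, config, subject_id,
             binarize = function(img) list(binary = binarize_st(img)))
}

#' Compare the two pipelines over a cohort
#'
#' Takes paired per-subject results of both pipeline branches and emits the
#' full comparison bundle: a cohort summary per method (the per-sector
#' mean/SD/quartile tables), Bland-Altman agreement statistics for each of
#' SkD, VD and VDI in each of the 9 sectors (27 rows, differences formed as
#' MHF minus ST), and the cohort-mean fragmentation and noise-reduction
#' figures with the fragmentation percent difference.
#'
#' @param mhf_results,st_results lists of successful branch results from
#'   [run_mhf_pipeline()] / [run_st_pipeline()], paired by position
#'   (>= 3 subjects with both branches).
#' @param config a [pipeline_config()] (supplies the Bland-Altman CI rule).
#' @return An object of class `method_comparison`: `summary_mhf`,
#'   `summary_st` (see [cohort_summary()]); `bland_altman`, a data frame
#'   with columns `metric`, `sector`, `sector_number`, `n`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `ci_low`, `ci_high`, `significant`;
#'   `agreement`, the underlying `bland_altman_stats` objects (named
#'   `metric.sector`); and `quality`, the per-method mean fragmentation and
#'   noise reduction plus `fragmentation_pct_diff`.
#' @export
compare_methods <- function(mhf_results, st_results,
                            config = pipeline_config()) {
  ok <- function(res) vapply(res, function(r) is.null(r$error), TRUE)
  keep <- ok(mhf_results) & ok(st_results)
  if (length(mhf_results) != length(st_results))
    stopf("cohorts must be paired by subject")
  if (sum(keep) < 3L)
    stopf("need at least 3 subjects with both successful branches (have %d)",
          sum(keep))
  mhf_results <- mhf_results[keep]; st_results <- st_results[keep]
  m_mhf <- do.call(rbind, lapply(mhf_results, `[[`, "metrics"))
  m_st <- do.call(rbind, lapply(st_results, `[[`, "metrics"))

  ba_rows <- list(); ba_objs <- list()
  for (metric in c("SkD", "VD", "VDI")) {
    for (lbl in etdrs_sector_labels) {
      x <- m_mhf[[metric]][m_mhf$sector == lbl]
      y <- m_st[[metric]][m_st$sector == lbl]
      ba <- bland_altman(x, y, ci_method = config$ci_method)
      ba_objs[[paste(metric, lbl, sep = ".")]] <- ba
      ba_rows[[length(ba_rows) + 1L]] <- data.frame(
        metric = metric, sector = lbl,
        sector_number = unname(etdrs_sector_numbers[lbl]), n = ba$n,
        mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
        loa_low = ba$loa_low, loa_high = ba$loa_high,
        ci_low = ba$ci_low, ci_high = ba$ci_high,
        significant = ba$significant)
    }
  }

  frag <- vapply(list(mhf_results, st_results), function(res)
    mean(vapply(res, function(r) r$quality$n_components, 0)), 0)
  noise <- vapply(list(mhf_results, st_results), function(res)
    mean(vapply(res, function(r) r$quality$noise_reduction, 0)), 0)
  structure(list(
    n = sum(keep),
    summary_mhf = cohort_summary(m_mhf),
    summary_st = cohort_summary(m_st),
    bland_altman = do.call(rbind, ba_rows),
    agreement = ba_objs,
    quality = list(mean_components_mhf = frag[1],
                   mean_components_st = frag[2],
                   fragmentation_pct_diff =
                     fragmentation_pct_diff(frag[1], frag[2]),
                   mean_noise_reduction_mhf = noise[1],
                   mean_noise_reduction_st = noise[2])),
    class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> %d subjects\n", x$n))
  cat(sprintf("  mean segments: MHF %.1f vs ST %.1f (%.1f%% more fragmented)\n",
              x$quality$mean_components_mhf, x$quality$mean_components_st,
              x$quality$fragmentation_pct_diff))
  cat(sprintf("  mean noise reduction: MHF %.1f%% vs ST %.1f%%\n",
              100 * x$quality$mean_noise_reduction_mhf,
              100 * x$quality$mean_noise_reduction_st))
  sig <- sum(x$bland_altman$significant)
  cat(sprintf("  Bland-Altman: %d of %d metric x sector cells significant\n",
              sig, nrow(x$bland_altman)))
  invisible(x)
}

#' Write comparison artifacts to disk
#'
#' Emits the per-subject metric CSV, the two cohort-summary CSVs and the
#' Bland-Altman CSV (27 rows), plus a JSON quality report.
#'
#' @param comparison a [compare_methods()] result.
#' @param mhf_results,st_results the cohorts it was built from.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_comparison <- function(comparison, mhf_results, st_results, dir) {
  stopifnot(inherits(comparison, "method_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    subject_metrics = file.path(dir, "subject_metrics.csv"),
    summary_mhf = file.path(dir, "summary_mhf.csv"),
    summary_st = file.path(dir, "summary_st.csv"),
    bland_altman = file.path(dir, "bland_altman.csv"),
    quality = file.path(dir, "quality.json"))
  all_metrics <- rbind(
    do.call(rbind, lapply(mhf_results, `[[`, "metrics")),
    do.call(rbind, lapply(st_results, `[[`, "metrics")))
  utils::write.csv(all_metrics, paths["subject_metrics"], row.names = FALSE)
  utils::write.csv(comparison$summary_mhf, paths["summary_mhf"],
                   row.names = FALSE)
  utils::write.csv(comparison$summary_st, paths["summary_st"],
                   row.names = FALSE)
  utils::write.csv(comparison$bland_altman, paths["bland_altman"],
                   row.names = FALSE)
  jsonlite::write_json(comparison$quality, paths["quality"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
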