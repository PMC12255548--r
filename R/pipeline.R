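#' Fit parameter maps for a whole cohort
#'
#' Runs [fit_qmaps()] on both sessions of every subject of a simulated (or
#' otherwise assembled) cohort.
#'
#' @param cohort Tibble from [simulate_cohort()]: columns `subject`, `type`,
#'   `study`.
#' @param ... Passed to [fit_qmaps()].
#' @return The cohort tibble with list-columns `fits` (per subject: list of
#'   two named map lists) and `regions` (the subject's [region_set()]).
#' @export
fit_cohort <- function(cohort, ...) {
  dplyr::mutate(
    cohort,
    fits = purrr::map(.data$study, function(st) {
      lapply(st$sessions, fit_qmaps, ...)
    }),
    regions = purrr::map(.data$study, function(st) st$truth$regions))
}

#' Per-subject ROI measurements of the qMRI parameters
#'
#' The ROI measurement is the median parameter value over each region's valid
#' voxels, per scan. Empty or fully-invalid region intersections yield `NA`
#' (missing-entry records, excluded downstream).
#'
#' @param fitted Tibble from [fit_cohort()].
#' @param regions_use Region names to measure.
#' @return A tibble: `subject`, `quantity`, `region`, `session`, `value`.
#' @export
cohort_roi_measurements <- function(fitted, regions_use = region_names) {
  purrr::pmap_dfr(
    fitted[c("subject", "fits", "regions")],
    function(subject, fits, regions) {
      grid <- expand.grid(quantity = names(fits[[1]]), region = regions_use,
                          session = seq_along(fits),
                          stringsAsFactors = FALSE)
      grid$subject <- subject
      grid$value <- purrr::pmap_dbl(
        grid[c("quantity", "region", "session")],
        function(quantity, region, session) {
          suppressWarnings(
            roi_measurement(fits[[session]][[quantity]],
                            region_mask(regions, region)))
        })
      tibble::as_tibble(grid[c("subject", "quantity", "region", "session",
                               "value")])
    })
}

#' Per-subject voxel-wise repeatability statistics of the qMRI parameters
#'
#' Computes the voxel %CV map of each quantity from the two sessions and
#' aggregates it to one `%wCV_voxel` per subject, quantity and region (root
#' mean square over the region's usable voxels).
#'
#' @inheritParams cohort_roi_measurements
#' @return A tibble: `subject`, `quantity`, `region`, `wcv`, `n_voxels`,
#'   `n_excluded`.
#' @export
cohort_voxel_stats <- function(fitted, regions_use = region_names) {
  purrr::pmap_dfr(
    fitted[c("subject", "fits", "regions")],
    function(subject, fits, regions) {
      purrr::map_dfr(names(fits[[1]]), function(q) {
        cvm <- voxel_cv_map(fits[[1]][[q]], fits[[2]][[q]])
        purrr::map_dfr(regions_use, function(rg) {
          cv <- cvm$cv[region_mask(regions, rg)]
          usable <- cv[!is.na(cv)]
          tibble::tibble(
            subject = subject, quantity = q, region = rg,
            wcv = if (length(usable)) wcv_voxel(usable) else NA_real_,
            n_voxels = length(usable),
            n_excluded = sum(is.na(cv)))
        })
      })
    })
}

#' End-to-end qMRI repeatability study
#'
#' The full analysis for the six qMRI parameters (plus the T2w image): fits
#' both sessions of every subject, computes ROI-mode and voxel-mode
#' repeatability records, tests the zone and tissue dependency of each
#' quantity, and classifies them.
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param alpha Significance level for the dependency tests.
#' @param ... Passed to [fit_qmaps()].
#' @return A list of class `qmri_repeatability`: `roi`, `voxel`
#'   (`repeatability_records`), `dependency_roi`, `dependency_voxel`
#'   (tibbles), `subject_types`, and `fitted` (the fitted cohort tibble).
#' @export
qmri_repeatability_study <- function(cohort, alpha = 0.05, ...) {
  fitted <- fit_cohort(cohort, ...)
  subject_types <- fitted[c("subject", "type")]
  roi <- roi_repeatability(cohort_roi_measurements(fitted))
  voxel <- voxel_repeatability(cohort_voxel_stats(fitted))
  structure(
    list(roi = roi, voxel = voxel,
         dependency_roi = dependency_table(roi, subject_types, alpha),
         dependency_voxel = dependency_table(voxel, subject_types, alpha),
         subject_types = subject_types, fitted = fitted),
    class = "qmri_repeatability")
}

#' @export
print.qmri_repeatability <- function(x, ...) {
  cat("<qmri_repeatability> ", nrow(x$subject_types), " subjects\n", sep = "")
  cat("ROI-mode %RC summary:\n")
  print(x$roi$summary, n = 15)
  invisible(x)
}

#' Per-subject feature repeatability statistics
#'
#' Extracts the 413 voxel-wise feature maps (7 images x 59 features) for both
#' sessions of every subject and computes, per feature, the ROI-mode
#' measurements (region medians per session) and the voxel-mode per-subject
#' `%wCV`. Feature quantities are identified as `"source|class|name"`.
#'
#' Texture extraction is the expensive stage; `mask_fun` controls which
#' voxels' windows are evaluated (default: the subject's eroded whole gland).
#'
#' @param fitted Tibble from [fit_cohort()].
#' @param regions_use Regions to measure.
#' @param mask_fun `function(region_set)` returning the extraction mask on
#'   the acquisition grid.
#' @param target,kernel_mm,bin_width See [extract_session_features()].
#' @return A list: `roi_measurements` (tibble: subject, quantity, region,
#'   session, value), `voxel_stats` (tibble: subject, quantity, region, wcv,
#'   n_voxels), `meta` (tibble: quantity, source, class, name).
#' @export
cohort_feature_stats <- function(fitted, regions_use = region_names,
                                 mask_fun = function(rs) rs$wg,
                                 target = 1, kernel_mm = 5, bin_width = 20) {
  roi_rows <- list(); vox_rows <- list(); meta <- NULL
  for (s in seq_len(nrow(fitted))) {
    regions <- fitted$regions[[s]]
    sf <- lapply(fitted$fits[[s]], function(maps) {
      extract_session_features(maps, mask_fun(regions),
                               mask_spacing = regions$spacing,
                               target = target, kernel_mm = kernel_mm,
                               bin_width = bin_width)
    })
    if (is.null(meta)) {
      meta <- dplyr::mutate(
        sf[[1]]$meta,
        quantity = paste(.data$source, .data$class, .data$name, sep = "|"))
    }
    iso_regions <- lapply(stats::setNames(regions_use, regions_use),
                          function(rg) {
                            resample_mask_isotropic(region_mask(regions, rg),
                                                    regions$spacing, target)
                          })
    idx <- sf[[1]]$sets[[1]]$index
    sub <- fitted$subject[s]
    for (src in names(sf[[1]]$sets)) {
      v1 <- sf[[1]]$sets[[src]]$values
      v2 <- sf[[2]]$sets[[src]]$values
      qid <- paste(src, colnames(v1), sep = "|")
      qid <- sub("^([^|]+)\\|([^_]+)_", "\\1|\\2|", qid)
      for (rg in regions_use) {
        in_rg <- iso_regions[[rg]][idx]
        a <- v1[in_rg, , drop = FALSE]
        b <- v2[in_rg, , drop = FALSE]
        med1 <- apply(a, 2, stats::median, na.rm = TRUE)
        med2 <- apply(b, 2, stats::median, na.rm = TRUE)
        roi_rows[[length(roi_rows) + 1]] <- tibble::tibble(
          subject = sub, quantity = rep(qid, 2), region = rg,
          session = rep(1:2, each = length(qid)),
          value = c(med1, med2))
        ok <- is.finite(a) & is.finite(b) & a > 0 & b > 0
        m <- (a + b) / 2
        ok <- ok & m > 0
        cv <- 100 * abs(a - b) / sqrt(2) / m
        cv[!ok] <- NA
        wcv <- sqrt(colMeans(cv^2, na.rm = TRUE))
        wcv[colSums(ok) == 0] <- NA
        vox_rows[[length(vox_rows) + 1]] <- tibble::tibble(
          subject = sub, quantity = qid, region = rg, wcv = wcv,
          n_voxels = colSums(ok))
      }
    }
  }
  roi <- dplyr::bind_rows(roi_rows)
  roi$value[!is.finite(roi$value)] <- NA
  list(roi_measurements = roi,
       voxel_stats = dplyr::bind_rows(vox_rows),
       meta = meta[c("quantity", "source", "class", "name")])
}

#' End-to-end feature repeatability study
#'
#' ROI- and voxel-mode repeatability, dependency classification and top-k
#' ranking for the 413 texture features.
#'
#' @inheritParams cohort_feature_stats
#' @param alpha Significance level.
#' @param k Ranking depth (default 50).
#' @return A list of class `feature_repeatability`: `roi`, `voxel`,
#'   `dependency_roi`, `dependency_voxel`, `top_roi`, `top_voxel`, `meta`.
#' @export
feature_repeatability_study <- function(fitted, regions_use = region_names,
                                        mask_fun = function(rs) rs$wg,
                                        target = 1, kernel_mm = 5,
                                        bin_width = 20, alpha = 0.05, k = 50) {
  stats_ <- cohort_feature_stats(fitted, regions_use, mask_fun, target,
                                 kernel_mm, bin_width)
  subject_types <- fitted[c("subject", "type")]
  roi <- roi_repeatability(stats_$roi_measurements)
  voxel <- voxel_repeatability(stats_$voxel_stats)
  dep_roi <- dependency_table(roi, subject_types, alpha)
  dep_voxel <- dependency_table(voxel, subject_types, alpha)
  structure(
    list(roi = roi, voxel = voxel,
         dependency_roi = dep_roi, dependency_voxel = dep_voxel,
         top_roi = rank_features(roi, dep_roi, stats_$meta, k),
         top_voxel = rank_features(voxel, dep_voxel, stats_$meta, k),
         meta = stats_$meta),
    class = "feature_repeatability")
}
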