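#' Percent coefficient of variation of repeated measurements
#'
#' `%CV = 100 * sd / mean` with the sample (n - 1) standard deviation; for the
#' usual two-repeat case this is `100 * |x1 - x2| / (sqrt(2) * mean)`.
#'
#' @param x Numeric vector of repeated measurements (length >= 2).
#' @return Percent CV, or `NA` when the mean is not positive (the statistic is
#'   undefined at mean zero for positive-valued quantities).
#' @export
percent_cv <- function(x) {
  stopifnot(length(x) >= 2)
  m <- mean(x)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  100 * stats::sd(x) / m
}

#' Within-subject %CV (root mean square)
#'
#' `wcv_roi` aggregates one %CV per subject into a single cohort value;
#' `wcv_voxel` aggregates voxel %CVs within one subject into one value per
#' subject. Both are the root mean square of their inputs; `NA`s (excluded
#' voxels/subjects) are dropped.
#'
#' @param cv Numeric vector of %CV values.
#' @return Percent within-subject CV.
#' @export
wcv_roi <- function(cv) {
  cv <- cv[!is.na(cv)]
  if (!length(cv)) stop("no %CV values to aggregate", call. = FALSE)
  sqrt(mean(cv^2))
}

#' @rdname wcv_roi
#' @export
wcv_voxel <- function(cv) {
  cv <- cv[!is.na(cv)]
  if (!length(cv)) return(NA_real_)
  sqrt(mean(cv^2))
}

#' Repeatability coefficient
#'
#' `%RC = 2.77 * %wCV`: the 95% bound on the difference between two repeated
#' measurements (the constant is `1.96 * sqrt(2)` rounded to two decimals, per
#' QIBA convention).
#'
#' @param wcv Within-subject %CV (>= 0).
#' @return Percent RC.
#' @export
repeatability_coefficient <- function(wcv) {
  stopifnot(all(wcv[!is.na(wcv)] >= 0))
  2.77 * wcv
}

#' Median of a map over a region
#'
#' The ROI measurement used throughout: the median of the valid voxels of a
#' parametric or feature map inside a region mask.
#'
#' @param map A [parametric_map()] (or `image_volume`).
#' @param region Logical array aligned to the map.
#' @return The median, or `NA` (with a warning) when no valid voxel falls in
#'   the region.
#' @export
roi_measurement <- function(map, region) {
  v <- map$values
  stopifnot(identical(dim(region), dim(v)))
  valid <- if (!is.null(map$valid)) map$valid else is.finite(v)
  x <- v[region & valid]
  if (!length(x)) {
    warning("region contains no valid voxels; measurement missing",
            call. = FALSE)
    return(NA_real_)
  }
  stats::median(x)
}

#' Voxel-wise %CV map of a test-retest pair
#'
#' Computes the two-repeat %CV at every voxel from two aligned maps. Voxels
#' invalid in either session, or with non-positive session values or a
#' non-positive mean, are excluded (NA) and counted.
#'
#' @param map1,map2 Aligned maps of the same quantity from the two sessions.
#' @param positive_only Exclude voxels with non-positive values (default TRUE;
#'   the %CV is undefined around zero). Quantities that legitimately cross
#'   zero (e.g. a signed score) should pass `FALSE`, in which case only
#'   non-positive *means* are excluded.
#' @return A list: `cv` (numeric array of voxel %CVs, NA where excluded) and
#'   `n_excluded`.
#' @export
voxel_cv_map <- function(map1, map2, positive_only = TRUE) {
  stop_if_unaligned(map1, map2, "session maps")
  v1 <- map1$values; v2 <- map2$values
  ok <- is.finite(v1) & is.finite(v2)
  if (!is.null(map1$valid)) ok <- ok & map1$valid
  if (!is.null(map2$valid)) ok <- ok & map2$valid
  if (positive_only) ok <- ok & v1 > 0 & v2 > 0
  m <- (v1 + v2) / 2
  ok <- ok & m > 0
  cv <- array(NA_real_, dim(v1))
  cv[ok] <- 100 * abs(v1[ok] - v2[ok]) / sqrt(2) / m[ok]
  list(cv = cv, n_excluded = sum(!ok))
}

region_names <- c("WG", "PZ", "nPZ", "tumor", "benign")

region_mask <- function(regions, name) {
  switch(name,
         WG = regions$wg, PZ = regions$pz, nPZ = regions$npz,
         tumor = regions$tumor, benign = regions$benign,
         stop("unknown region ", name, call. = FALSE))
}

#' ROI-mode repeatability records
#'
#' From per-subject, per-session ROI measurements to the cohort repeatability
#' table: per subject the two-session %CV, per cohort the root-mean-square
#' %wCV and `%RC = 2.77 %wCV`, for every quantity x region.
#'
#' @param measurements Tibble with columns `subject`, `quantity`, `region`,
#'   `session`, `value` (one row per subject x quantity x region x session).
#' @return A list of class `repeatability_records` with `mode = "ROI"`,
#'   `subject_stats` (tibble: subject, quantity, region, cv) and `summary`
#'   (tibble: quantity, region, mode, wcv, rc, n_subjects).
#' @export
roi_repeatability <- function(measurements) {
  subject_stats <- measurements |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::summarise(n_sessions = dplyr::n(),
                     cv = if (dplyr::n() >= 2) percent_cv(.data$value) else NA_real_,
                     .by = c("subject", "quantity", "region"))
  summary <- subject_stats |>
    dplyr::filter(!is.na(.data$cv)) |>
    dplyr::summarise(wcv = wcv_roi(.data$cv), n_subjects = dplyr::n(),
                     .by = c("quantity", "region")) |>
    dplyr::mutate(mode = "ROI", rc = repeatability_coefficient(.data$wcv),
                  .after = "region")
  structure(list(mode = "ROI", subject_stats = subject_stats,
                 summary = summary),
            class = "repeatability_records")
}

#' Voxel-mode repeatability records
#'
#' From per-subject voxel %CV maps to per-subject `%wCV_voxel` (root mean
#' square over a region's voxels) and per-subject `%RC_voxel`; the cohort
#' summary reports the median and range of the per-subject %RCs.
#'
#' @param voxel_stats Tibble with columns `subject`, `quantity`, `region`,
#'   `wcv`, `n_voxels` (one row per subject x quantity x region), e.g. from
#'   [study_voxel_stats()].
#' @return A list of class `repeatability_records` with `mode = "voxel"`,
#'   `subject_stats` (adds `rc` per subject) and `summary` (tibble: quantity,
#'   region, mode, rc = median per-subject %RC, rc_min, rc_max, n_subjects).
#' @export
voxel_repeatability <- function(voxel_stats) {
  subject_stats <- voxel_stats |>
    dplyr::mutate(rc = repeatability_coefficient(.data$wcv))
  summary <- subject_stats |>
    dplyr::filter(!is.na(.data$rc)) |>
    dplyr::summarise(rc_min = 2.77 * min(.data$wcv),
                     rc_max = 2.77 * max(.data$wcv),
                     wcv = stats::median(.data$wcv),
                     rc = 2.77 * stats::median(.data$wcv),
                     n_subjects = dplyr::n(),
                     .by = c("quantity", "region")) |>
    dplyr::relocate("rc_min", "rc_max", .after = "wcv") |>
    dplyr::mutate(mode = "voxel", .after = "region")
  structure(list(mode = "voxel", subject_stats = subject_stats,
                 summary = summary),
            class = "repeatability_records")
}

#' @export
print.repeatability_records <- function(x, ...) {
  cat("<repeatability_records> mode ", x$mode, ", ",
      nrow(x$summary), " quantity x region cells\n", sep = "")
  print(x$summary, n = 10)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy repeatability records
#'
#' @param x A `repeatability_records` object.
#' @param ... Unused.
#' @return The summary tibble (one row per quantity x region).
#' @method tidy repeatability_records
#' @export
tidy.repeatability_records <- function(x, ...) x$summary

#' @rdname tidy.repeatability_records
#' @method glance repeatability_records
#' @export
glance.repeatability_records <- function(x, ...) {
  tibble::tibble(mode = x$mode,
                 n_quantities = dplyr::n_distinct(x$summary$quantity),
                 n_regions = dplyr::n_distinct(x$summary$region),
                 n_subjects = max(x$summary$n_subjects))
}
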