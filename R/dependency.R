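#' Zone / tissue dependency of repeatability
#'
#' Tests whether the repeatability of a quantity differs between two sets of
#' ROIs with a two-tailed paired t test across subjects, following the study
#' design: the zone contrast (PZ vs nPZ) uses all subjects; the tissue
#' contrast (tumor vs benign) uses patients only. ROI mode pairs the
#' per-subject `%CV_ROI` values; voxel mode pairs the per-subject
#' `%wCV_voxel` values. Subjects missing either member of a pair are dropped
#' pairwise (with the count recorded); fewer than 3 complete pairs makes the
#' contrast untestable rather than silently non-significant. A degenerate
#' paired t (zero variance of a nonzero mean difference) is reported
#' significant at the numerical floor and flagged.
#'
#' @param records A `repeatability_records` object ([roi_repeatability()] or
#'   [voxel_repeatability()]).
#' @param quantity Quantity identifier to test.
#' @param contrast `"zone"` (PZ vs nPZ) or `"tissue"` (tumor vs benign).
#' @param subject_types Optional tibble `subject`, `type`
#'   (`"patient"`/`"volunteer"`); required for the tissue contrast, which
#'   keeps patients only.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble of class `rc_dependency`: `quantity`, `contrast`,
#'   `mode`, `t`, `p`, `significant`, `degenerate`, `n_pairs`,
#'   `n_dropped`, `testable`.
#' @export
compare_repeatability <- function(records, quantity,
                                  contrast = c("zone", "tissue"),
                                  subject_types = NULL, alpha = 0.05) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(records, "repeatability_records"))
  regions <- if (contrast == "zone") c("PZ", "nPZ") else c("tumor", "benign")
  metric <- if (records$mode == "ROI") "cv" else "wcv"
  df <- records$subject_stats |>
    dplyr::filter(.data$quantity == !!quantity, .data$region %in% regions)
  if (contrast == "tissue" && !is.null(subject_types)) {
    patients <- subject_types$subject[subject_types$type == "patient"]
    df <- dplyr::filter(df, .data$subject %in% patients)
  }
  wide <- df |>
    dplyr::select("subject", "region", dplyr::all_of(metric)) |>
    tidyr::pivot_wider(names_from = "region", values_from = dplyr::all_of(metric))
  for (r in regions) if (!r %in% names(wide)) wide[[r]] <- NA_real_
  complete <- stats::complete.cases(wide[regions])
  n_dropped <- sum(!complete)
  x <- wide[[regions[1]]][complete]
  y <- wide[[regions[2]]][complete]
  out <- tibble::tibble(
    quantity = quantity, contrast = contrast, mode = records$mode,
    t = NA_real_, p = NA_real_, significant = NA, degenerate = FALSE,
    n_pairs = length(x), n_dropped = n_dropped, testable = length(x) >= 3)
  if (!out$testable) return(structure(out, class = c("rc_dependency",
                                                     class(out))))
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      out$t <- 0; out$p <- 1; out$significant <- FALSE
    } else {
      out$t <- sign(mean(d)) * Inf
      out$p <- .Machine$double.xmin
      out$significant <- TRUE
      out$degenerate <- TRUE
    }
  } else {
    tt <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
    out$t <- unname(tt$statistic)
    out$p <- tt$p.value
    out$significant <- out$p < alpha
  }
  structure(out, class = c("rc_dependency", class(out)))
}

#' Classify a quantity's repeatability dependence
#'
#' Combines the zone and tissue contrasts into the four-way category used to
#' decide whether region-specific repeatability thresholds are needed:
#' `"both"`, `"tissue only"`, `"zone only"`, `"neither"` (or
#' `"unclassified"` when either contrast is untestable).
#'
#' @param zone_result,tissue_result One-row `rc_dependency` tibbles.
#' @return A character scalar.
#' @export
classify_dependency <- function(zone_result, tissue_result) {
  z_ok <- isTRUE(zone_result$testable)
  t_ok <- isTRUE(tissue_result$testable)
  if (!z_ok || !t_ok) return("unclassified")
  z <- isTRUE(zone_result$significant)
  t <- isTRUE(tissue_result$significant)
  if (z && t) "both" else if (t) "tissue only" else if (z) "zone only" else "neither"
}

#' Dependency table for every quantity
#'
#' Runs both contrasts for each quantity present in the records and classifies
#' each. A Benjamini-Hochberg adjusted p value is reported alongside for
#' transparency; classification uses the unadjusted per-quantity tests at
#' `alpha`, matching the per-feature testing design.
#'
#' @inheritParams compare_repeatability
#' @return A tibble: `quantity`, `mode`, `zone_t`, `zone_p`, `tissue_t`,
#'   `tissue_p`, `zone_p_bh`, `tissue_p_bh`, `category`.
#' @export
dependency_table <- function(records, subject_types = NULL, alpha = 0.05) {
  quantities <- unique(records$subject_stats$quantity)
  rows <- lapply(quantities, function(q) {
    z <- compare_repeatability(records, q, "zone", subject_types, alpha)
    t <- compare_repeatability(records, q, "tissue", subject_types, alpha)
    tibble::tibble(quantity = q, mode = records$mode,
                   zone_t = z$t, zone_p = z$p, tissue_t = t$t, tissue_p = t$p,
                   category = classify_dependency(z, t))
  })
  out <- dplyr::bind_rows(rows)
  out$zone_p_bh <- stats::p.adjust(out$zone_p, method = "BH")
  out$tissue_p_bh <- stats::p.adjust(out$tissue_p, method = "BH")
  dplyr::relocate(out, "category", .after = dplyr::last_col())
}
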