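#' Rank features by repeatability
#'
#' Pools all feature repeatability records and ranks features by their %RC to
#' obtain the top `k` most repeatable ones. Each feature is summarised by a
#' single %RC according to its dependency category: features whose
#' repeatability depends on neither tissue type nor anatomical zone use the
#' whole-gland %RC; features with a dependency use the *largest* %RC over
#' their relevant regions (PZ/nPZ for a zone dependency, tumor/benign for a
#' tissue dependency, all four for both). In voxel mode the per-region %RC is
#' the median of the per-subject %RC values (already so in the summary).
#' Features with a missing %RC in a required region, or an unclassified
#' category, are excluded with a message. Ties are broken lexicographically by
#' (source, class, name) so rankings are deterministic.
#'
#' @param records A `repeatability_records` object whose quantities are
#'   feature identifiers (`source|class|name`).
#' @param categories Tibble `quantity`, `category` from [dependency_table()].
#' @param meta Tibble `quantity`, `source`, `class`, `name` describing each
#'   feature (e.g. from [cohort_feature_stats()]).
#' @param k Number of features to return (all, ordered, if fewer exist).
#' @return A tibble: `rank`, `source`, `class`, `name`, `category`, `rc`,
#'   ascending in `rc`.
#' @export
rank_features <- function(records, categories, meta, k = 50) {
  stopifnot(inherits(records, "repeatability_records"))
  summ <- records$summary
  rule <- function(category) {
    switch(category,
           "neither" = "WG",
           "zone only" = c("PZ", "nPZ"),
           "tissue only" = c("tumor", "benign"),
           "both" = c("PZ", "nPZ", "tumor", "benign"),
           NULL)
  }
  rows <- lapply(seq_len(nrow(categories)), function(r) {
    q <- categories$quantity[r]
    regions <- rule(categories$category[r])
    if (is.null(regions)) return(NULL)
    rc <- summ$rc[summ$quantity == q & summ$region %in% regions]
    rc <- rc[!is.na(rc)]
    if (length(rc) < length(regions)) return(NULL)
    tibble::tibble(quantity = q, category = categories$category[r],
                   rc = max(rc))
  })
  empty <- tibble::tibble(quantity = character(), category = character(),
                          rc = numeric())
  kept <- dplyr::bind_rows(c(list(empty), rows))
  n_excluded <- nrow(categories) - nrow(kept)
  if (n_excluded > 0) {
    message("rank_features: excluded ", n_excluded,
            " feature(s) with missing %RC or unclassified category")
  }
  out <- kept |>
    dplyr::left_join(meta, by = "quantity") |>
    dplyr::arrange(.data$rc, .data$source, .data$class, .data$name) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1) |>
    dplyr::select("rank", "source", "class", "name", "category", "rc")
  out
}
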