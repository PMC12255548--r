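test_that("percent CV follows the QIBA two-repeat definition", {
  expect_identical(percent_cv(c(10, 10)), 0)
  expect_equal(percent_cv(c(8, 12)), 28.28427, tolerance = 1e-6)  # 100*2*sqrt(2)/10
  expect_equal(percent_cv(c(8, 12)), 100 * abs(8 - 12) / sqrt(2) / 10)
  # scale invariance
  set.seed(2)
  x <- runif(2, 1, 5)
  for (c_ in c(0.1, 3, 1e4)) {
    expect_equal(percent_cv(c_ * x), percent_cv(x), tolerance = 1e-12)
  }
  expect_true(is.na(percent_cv(c(-3, 1))))
  expect_error(percent_cv(5))
})

test_that("within-subject CVs aggregate as root mean squares", {
  expect_identical(wcv_roi(rep(5, 7)), 5)
  expect_equal(wcv_roi(c(3, 4)), sqrt(12.5))
  expect_error(wcv_roi(numeric(0)), "no %CV")
  set.seed(4)
  cvs <- runif(20, 0, 30)
  expect_gte(wcv_roi(cvs), mean(cvs))   # RMS >= arithmetic mean
  expect_identical(wcv_voxel(rep(10, 4)), 10)
  expect_equal(wcv_voxel(c(0, 10)), sqrt(50))
  # appending a below-RMS value never increases the RMS
  expect_lte(wcv_voxel(c(cvs, 0)), wcv_voxel(cvs))
})

test_that("the repeatability coefficient is exactly 2.77 x wCV", {
  expect_identical(repeatability_coefficient(0), 0)
  expect_identical(repeatability_coefficient(10), 27.7)
  w <- c(0.3, 5, 42.17)
  expect_identical(repeatability_coefficient(w) / w, rep(2.77, 3))
})

test_that("ROI measurements are medians over valid region voxels", {
  d <- c(3, 1, 1)
  m <- parametric_map(array(c(1, 2, 100), d), "ADC")
  region <- array(TRUE, d)
  expect_identical(roi_measurement(m, region), 2)
  const <- parametric_map(array(7, d), "T1")
  expect_identical(roi_measurement(const, region), 7)
  invalid <- parametric_map(array(NaN, d), "ADC")
  expect_warning(out <- roi_measurement(invalid, region), "no valid voxels")
  expect_true(is.na(out))
})

test_that("voxel CV maps exclude invalid and non-positive voxels", {
  d <- c(2, 2, 1)
  m1 <- parametric_map(array(c(10, 5, -1, NaN), d), "T2w")
  m2 <- parametric_map(array(c(10, 15, 1, 2), d), "T2w")
  out <- voxel_cv_map(m1, m2)
  expect_identical(out$cv[1, 1, 1], 0)
  expect_equal(out$cv[2, 1, 1], 100 * 10 / sqrt(2) / 10)
  expect_true(is.na(out$cv[1, 2, 1]))   # negative session value
  expect_true(is.na(out$cv[2, 2, 1]))   # invalid session value
  expect_identical(out$n_excluded, 2L)
})

test_that("repeatability records keep %RC = 2.77 x %wCV exactly", {
  set.seed(6)
  meas <- tidyr::expand_grid(subject = 1:5, quantity = c("A", "B"),
                             region = c("WG", "PZ"), session = 1:2)
  meas$value <- runif(nrow(meas), 50, 150)
  roi <- roi_repeatability(meas)
  expect_identical(tidy(roi)$rc, 2.77 * tidy(roi)$wcv)
  expect_identical(nrow(tidy(roi)), 4L)
  expect_true(all(tidy(roi)$n_subjects == 5))
  # hand-check one cell: subject 1, quantity A, region WG
  v <- meas$value[meas$subject == 1 & meas$quantity == "A" & meas$region == "WG"]
  cv1 <- 100 * sd(v) / mean(v)
  expect_equal(roi$subject_stats$cv[roi$subject_stats$subject == 1 &
                                      roi$subject_stats$quantity == "A" &
                                      roi$subject_stats$region == "WG"], cv1)
  vox <- voxel_repeatability(
    tibble::tibble(subject = rep(1:4, 2), quantity = rep(c("A", "B"), each = 4),
                   region = "WG", wcv = c(1:4, 2:5), n_voxels = 100))
  expect_identical(vox$subject_stats$rc, 2.77 * vox$subject_stats$wcv)
  s <- tidy(vox)
  expect_equal(s$rc[s$quantity == "A"], 2.77 * 2.5)  # median of 1..4
  expect_equal(s$rc_min[s$quantity == "A"], 2.77 * 1)
  expect_equal(s$rc_max[s$quantity == "B"], 2.77 * 5)
})

test_that("paired contrasts match the textbook t statistic", {
  x <- c(10, 12, 9, 11); y <- c(16, 20, 15, 19)
  stats_tbl <- tibble::tibble(
    subject = rep(1:4, 2), quantity = "Q",
    region = rep(c("PZ", "nPZ"), each = 4),
    cv = c(x, y))
  rec <- structure(list(mode = "ROI", subject_stats = stats_tbl),
                   class = "repeatability_records")
  res <- compare_repeatability(rec, "Q", "zone")
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_hand)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df = 3))
  expect_true(res$significant)
  expect_identical(res$n_pairs, 4L)
})

test_that("degenerate and null paired contrasts are handled explicitly", {
  base <- tibble::tibble(subject = rep(1:3, 2), quantity = "Q",
                         region = rep(c("PZ", "nPZ"), each = 3))
  # identical vectors: t = 0, p = 1
  rec0 <- structure(list(mode = "ROI",
                         subject_stats = dplyr::mutate(base, cv = rep(c(4, 5, 6), 2))),
                    class = "repeatability_records")
  res0 <- compare_repeatability(rec0, "Q", "zone")
  expect_identical(res0$t, 0)
  expect_identical(res0$p, 1)
  expect_false(res0$significant)
  # constant nonzero difference: degenerate, significant at the floor
  rec1 <- structure(list(mode = "ROI",
                         subject_stats = dplyr::mutate(base, cv = c(1, 2, 3, 2, 3, 4))),
                    class = "repeatability_records")
  res1 <- compare_repeatability(rec1, "Q", "zone")
  expect_true(res1$degenerate)
  expect_true(res1$significant)
  expect_lt(res1$p, 1e-300)
  # fewer than 3 complete pairs: untestable, never silently significant
  rec2 <- structure(list(mode = "ROI",
                         subject_stats = dplyr::mutate(base, cv = c(1, 2, NA, 2, 3, 4))),
                    class = "repeatability_records")
  res2 <- compare_repeatability(rec2, "Q", "zone")
  expect_false(res2$testable)
  expect_true(is.na(res2$significant))
  expect_identical(res2$n_dropped, 1L)
})

test_that("the tissue contrast uses patient subjects only", {
  stats_tbl <- tidyr::expand_grid(subject = 1:6, quantity = "Q",
                                  region = c("tumor", "benign"))
  set.seed(9)
  # patients 1-3 have a strong effect; volunteers would dilute it
  stats_tbl$cv <- ifelse(stats_tbl$region == "tumor" & stats_tbl$subject <= 3,
                         20 + rnorm(nrow(stats_tbl), 0, 0.1),
                         5 + rnorm(nrow(stats_tbl), 0, 0.1))
  rec <- structure(list(mode = "ROI", subject_stats = stats_tbl),
                   class = "repeatability_records")
  types <- tibble::tibble(subject = 1:6,
                          type = rep(c("patient", "volunteer"), each = 3))
  res <- compare_repeatability(rec, "Q", "tissue", subject_types = types)
  expect_identical(res$n_pairs, 3L)
  expect_true(res$significant)
})

test_that("dependency categories follow the two significance flags", {
  mk <- function(sig, testable = TRUE) {
    tibble::tibble(significant = sig, testable = testable)
  }
  expect_identical(classify_dependency(mk(TRUE), mk(TRUE)), "both")
  expect_identical(classify_dependency(mk(FALSE), mk(TRUE)), "tissue only")
  expect_identical(classify_dependency(mk(TRUE), mk(FALSE)), "zone only")
  expect_identical(classify_dependency(mk(FALSE), mk(FALSE)), "neither")
  expect_identical(classify_dependency(mk(NA, testable = FALSE), mk(TRUE)),
                   "unclassified")
})

test_that("feature ranking applies the category-specific %RC rule", {
  summ <- tibble::tibble(
    quantity = c(rep("A|GLCM|x", 1), rep("B|GLCM|y", 5)),
    region = c("WG", "WG", "PZ", "nPZ", "tumor", "benign"),
    rc = c(5, 4, 2, 3, 6, 1))
  records <- structure(list(mode = "ROI", summary = summ),
                       class = "repeatability_records")
  categories <- tibble::tibble(quantity = c("A|GLCM|x", "B|GLCM|y"),
                               category = c("neither", "tissue only"))
  meta <- tibble::tibble(quantity = c("A|GLCM|x", "B|GLCM|y"),
                         source = c("A", "B"), class = "GLCM",
                         name = c("x", "y"))
  out <- rank_features(records, categories, meta, k = 50)
  # A uses WG (5); B uses max(tumor, benign) = 6 -> A ranks first
  expect_identical(out$source, c("A", "B"))
  expect_identical(out$rc, c(5, 6))
  # k larger than the feature count returns everything, ordered
  expect_identical(nrow(rank_features(records, categories, meta, k = 1e6)), 2L)
  # ties break lexicographically and deterministically
  summ2 <- tibble::tibble(quantity = c("B|GLCM|y", "A|GLCM|x"),
                          region = "WG", rc = c(3, 3))
  rec2 <- structure(list(mode = "ROI", summary = summ2),
                    class = "repeatability_records")
  cat2 <- tibble::tibble(quantity = c("B|GLCM|y", "A|GLCM|x"),
                         category = "neither")
  out2 <- rank_features(rec2, cat2, meta, k = 2)
  expect_identical(out2$source, c("A", "B"))
  # missing %RC in a required region -> excluded with a message
  cat3 <- tibble::tibble(quantity = "A|GLCM|x", category = "zone only")
  expect_message(out3 <- rank_features(records, cat3, meta), "excluded 1")
  expect_identical(nrow(out3), 0L)
})

test_that("voxel-mode %RC dominates ROI-mode %RC on the homogeneous phantom", {
  spec <- small_spec(pz_dwi_noise_inflation = 1, drift_sd = 0,
                     jitter_mm = 0, jitter_deg = 0)
  co <- simulate_cohort(n_patients = 0, n_volunteers = 5, spec = spec,
                        seed = 55, series = "dwi")
  fitted <- dplyr::mutate(
    co,
    fits = purrr::map(study, function(st) {
      lapply(st$sessions, function(s) list(ADC = fit_adc(s$dwi)))
    }),
    regions = purrr::map(study, function(st) st$truth$regions))
  roi <- tidy(roi_repeatability(cohort_roi_measurements(fitted, "WG")))
  vox <- tidy(voxel_repeatability(cohort_voxel_stats(fitted, "WG")))
  expect_gt(vox$rc, roi$rc)   # region medians average noise away
})

test_that("tidy and glance return summary tibbles", {
  set.seed(10)
  meas <- tidyr::expand_grid(subject = 1:3, quantity = "ADC",
                             region = c("WG", "PZ"), session = 1:2)
  meas$value <- runif(nrow(meas), 90, 110)
  roi <- roi_repeatability(meas)
  expect_s3_class(tidy(roi), "tbl_df")
  g <- glance(roi)
  expect_identical(g$mode, "ROI")
  expect_identical(g$n_quantities, 1L)
  expect_identical(g$n_regions, 2L)
})
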