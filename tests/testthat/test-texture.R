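test_that("isotropic resampling preserves what interpolation must preserve", {
  # already isotropic: untouched
  v <- image_volume(array(rnorm(4 * 4 * 4), c(4, 4, 4)))
  expect_identical(resample_isotropic(v, 1), v)
  # constants stay constant at any spacing
  cv <- image_volume(array(7.5, c(6, 6, 4)), spacing = c(1.5, 1.5, 3))
  out <- resample_isotropic(cv, 1)
  expect_equal(out$spacing, c(1, 1, 1))
  expect_equal(max(abs(out$values - 7.5)), 0, tolerance = 1e-12)
  expect_identical(dim(out$values), c(9L, 9L, 12L))
  # a linear ramp is reproduced by trilinear interpolation (away from edges)
  d <- c(12, 6, 4)
  ramp <- image_volume(array(rep(seq_len(d[1]) * 2, d[2] * d[3]), d),
                       spacing = c(2, 2, 2))
  riso <- resample_isotropic(ramp, 1)
  # physical coordinate of output voxel centres along x
  xs <- ((seq_len(dim(riso$values)[1]) - 0.5) * 1 - 1) / 2  # input index
  expected <- (xs + 1) * 2
  core <- 3:(length(xs) - 2)
  expect_equal(riso$values[core, 3, 3], expected[core], tolerance = 1e-10)
  # mask resampling is nearest-neighbour and stays boolean
  m <- array(FALSE, c(6, 6, 4)); m[2:4, 2:4, 2:3] <- TRUE
  miso <- qmrirep:::resample_mask_isotropic(m, c(1.5, 1.5, 3), 1)
  expect_type(miso, "logical")
  expect_identical(dim(miso), c(9L, 9L, 12L))
})

test_that("normalisation z-scores, scales by 100 and clips to [-300, 300]", {
  set.seed(5)
  # bounded intensities: nothing reaches the +-3 sd clip, so the pure z-score
  # properties are visible on the output
  v <- image_volume(array(runif(1000, 20, 80), c(10, 10, 10)))
  out <- normalize_image(v)$values
  expect_lt(abs(mean(out)), 1e-9)
  expect_equal(sqrt(mean(out^2)), 100, tolerance = 1e-9)
  # extreme outliers are clipped into the stated range
  v$values[1, 1, 1] <- 1e6
  out2 <- normalize_image(v)$values
  expect_gte(min(out2), -300)
  expect_lte(max(out2), 300)
  expect_equal(max(out2), 300)
  # hand case: {0, 10} with population sd 5 -> {-100, +100}
  two <- image_volume(array(c(0, 10), c(2, 1, 1)))
  expect_equal(as.vector(normalize_image(two)$values), c(-100, 100))
  expect_error(normalize_image(image_volume(array(3, c(2, 2, 2)))),
               "zero intensity spread")
})

test_that("fixed-bin-width discretisation bins from the global minimum", {
  v <- array(c(0, 19.9, 20, 0), c(4, 1, 1))
  expect_identical(as.vector(discretize(v, 20))[1:3], c(1L, 1L, 2L))
  expect_true(all(discretize(array(5, c(3, 3, 1)), 20) == 1L))
  # the full normalised range -300..300 fits in at most 31 labels
  r <- array(seq(-300, 300, length.out = 64), c(64, 1, 1))
  expect_lte(max(discretize(r, 20)), 31L)
  # NaN voxels carry NA labels
  w <- array(c(NaN, 1, 2, 3), c(4, 1, 1))
  expect_true(is.na(discretize(w, 1)[1]))
})

test_that("texture matrices match brute-force enumeration on small windows", {
  dirs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  set.seed(31)
  for (case in 1:25) {
    nr <- sample(3:7, 1); nc <- sample(3:7, 1)
    ng <- sample(1:4, 1)
    W <- matrix(sample(seq_len(ng), nr * nc, replace = TRUE), nr, nc)
    for (dir in dirs) {
      expect_identical(unname(glcm_matrix(W, dir)), unname(bf_glcm(W, dir)))
      expect_identical(unname(glrlm_matrix(W, dir)), unname(bf_glrlm(W, dir)))
    }
    expect_identical(unname(gldm_matrix(W)), unname(bf_gldm(W)))
    ng_cmp <- ngtdm_components(W)
    ng_bf <- bf_ngtdm(W)
    expect_identical(ng_cmp$levels, ng_bf$levels)
    expect_identical(ng_cmp$n, ng_bf$n)
    expect_equal(ng_cmp$s, ng_bf$s, tolerance = 1e-12)
  }
})

test_that("a two-level checkerboard reproduces hand-enumerated GLCM counts", {
  W <- outer(1:4, 1:4, function(r, c) ((r + c) %% 2) + 1L)
  # horizontal: every adjacent pair differs -> 12 ordered pairs each way
  M <- glcm_matrix(W, c(0, 1))
  expect_identical(unname(M), matrix(c(0L, 12L, 12L, 0L), 2))
  # diagonal: all pairs equal -> 9 pairs per level, both orderings
  Md <- glcm_matrix(W, c(1, 1))
  expect_identical(unname(Md), matrix(c(10L, 0L, 0L, 8L), 2))
  # averaged GLCM contrast over the 4 directions: (1 + 1 + 0 + 0) / 4
  feats <- window_texture_features(W)
  expect_equal(unname(feats["GLCM_Contrast"]), 0.5)
})

test_that("degenerate single-level windows follow the stated conventions", {
  feats <- window_texture_features(matrix(4L, 5, 5))
  expect_equal(unname(feats["GLCM_Contrast"]), 0)
  expect_equal(unname(feats["GLCM_Correlation"]), 1)
  expect_equal(unname(feats["GLCM_MCC"]), 1)
  expect_equal(unname(feats["GLCM_Imc1"]), 0)
  expect_equal(unname(feats["NGTDM_Coarseness"]), 1e6)
  expect_equal(unname(feats["NGTDM_Contrast"]), 0)
  expect_equal(unname(feats["GLRLM_RunPercentage"]), (5 + 5 + 9 + 9) / 4 / 25)
  expect_equal(unname(feats["GLDM_LargeDependenceEmphasis"]),
               sum(c(rep(4, 4), rep(6, 12), rep(9, 9))^2) / 25)
})

test_that("the extraction engine agrees with the per-window oracle", {
  set.seed(17)
  d <- c(12, 11, 3)
  vol <- image_volume(array(rnorm(prod(d), 0, 40), d))
  mask <- array(FALSE, d); mask[3:10, 3:9, ] <- TRUE
  fms <- extract_voxel_features(vol, mask, kernel_mm = 5, bin_width = 20)
  expect_identical(ncol(fms$values), 59L)
  labels <- discretize(vol, 20)
  idx <- sample(seq_along(fms$index), 25)
  for (r in idx) {
    co <- arrayInd(fms$index[r], d)
    W <- labels[max(1, co[1] - 2):min(d[1], co[1] + 2),
                max(1, co[2] - 2):min(d[2], co[2] + 2), co[3]]
    expect_equal(unname(fms$values[r, ]),
                 unname(window_texture_features(W)), tolerance = 1e-12)
  }
  # deterministic: identical input gives bit-identical maps
  fms2 <- extract_voxel_features(vol, mask, kernel_mm = 5, bin_width = 20)
  expect_identical(fms$values, fms2$values)
  # kernel below 3 voxels is rejected
  expect_error(extract_voxel_features(vol, mask, kernel_mm = 2), "3 voxels")
})

test_that("features are invariant under a global intensity shift", {
  set.seed(23)
  d <- c(10, 10, 2)
  base <- array(rnorm(prod(d), 0, 30), d)
  mask <- array(FALSE, d); mask[3:8, 3:8, ] <- TRUE
  go <- function(x) {
    extract_voxel_features(normalize_image(image_volume(x)), mask)$values
  }
  expect_equal(go(base), go(base + 150), tolerance = 1e-10)
})

test_that("window edge handling crops windows instead of padding", {
  d <- c(6, 6, 1)
  set.seed(9)
  vol <- image_volume(array(rnorm(prod(d), 0, 25), d))
  mask <- array(TRUE, d)
  fms <- extract_voxel_features(vol, mask, kernel_mm = 5, bin_width = 10)
  labels <- discretize(vol, 10)
  # the corner voxel sees only its 3x3 in-slice sub-window
  corner <- which(fms$index == 1)
  expect_equal(unname(fms$values[corner, ]),
               unname(window_texture_features(labels[1:3, 1:3, 1])),
               tolerance = 1e-12)
})

test_that("a session yields 59 maps per image and 413 in total", {
  # miniature session: tiny grid keeps this structural check fast
  spec <- small_spec()
  st <- simulate_study(spec, seed = 3)
  maps <- fit_qmaps(st$sessions[[1]])
  mask <- st$truth$regions$wg
  mask[, , c(1:2, 4:6)] <- FALSE       # central acquisition slice only
  sf <- extract_session_features(maps, mask, mask_spacing = spec$spacing)
  expect_length(sf$sets, 7)
  for (s in sf$sets) expect_identical(ncol(s$values), 59L)
  expect_identical(nrow(sf$meta), 413L)
  expect_false(any(duplicated(
    paste(sf$meta$source, sf$meta$class, sf$meta$name))))
})
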