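test_that("two-point ADC inverts the mono-exponential model exactly", {
  b <- c(0, 50, 200, 800)
  adc_true <- 1.0e-3
  dwi <- signal_series(function(b) 1000 * exp(-b * adc_true), b, "b-value")
  m <- fit_adc(dwi)
  expect_true(all(m$valid))
  expect_equal(unique(as.vector(m$values)), adc_true, tolerance = 1e-12)
  # equal signals at both b-values -> ADC = 0
  flat <- signal_series(function(b) 500, c(50, 800), "b-value")
  expect_true(all(fit_adc(flat)$values == 0))
  # contract violations
  expect_error(fit_adc(dwi, b_pair = c(50, 50)), "differ")
  expect_error(fit_adc(dwi, b_pair = c(50, 700)), "700")
  # non-positive signal invalidates the voxel
  vols <- lapply(c(50, 800), function(b) image_volume(array(100, c(2, 2, 2))))
  vols[[2]]$values[1, 1, 1] <- 0
  m2 <- fit_adc(acquisition_series(vols, "b-value", c(50, 800)))
  expect_false(m2$valid[1, 1, 1])
  expect_true(is.nan(m2$values[1, 1, 1]))
  expect_identical(attr(m2, "fit_report")$n_nonpositive_signal, 1L)
})

test_that("simplified IVIM recovers a single-compartment signal exactly", {
  b <- c(0, 20, 50, 100, 200, 300, 400, 600, 800)
  d_true <- 1.3e-3
  dwi <- signal_series(function(b) 800 * exp(-b * d_true), b, "b-value")
  fit <- fit_ivim_simplified(dwi)
  expect_equal(unique(as.vector(fit$D$values)), d_true, tolerance = 1e-10)
  expect_equal(max(abs(fit$f$values)), 0, tolerance = 1e-10)
  expect_error(fit_ivim_simplified(signal_series(function(b) exp(-b), c(50, 300, 800),
                                                 "b-value")),
               "b = 0")
})

test_that("IVIM on two-compartment signals matches the lm() oracle and the
           pseudo-diffusion leverage bound", {
  b <- c(0, 20, 50, 100, 200, 300, 400, 600, 800)
  f_true <- 0.10; d_true <- 1.2e-3; dstar <- 10 * d_true
  s <- 900 * (f_true * exp(-b * dstar) + (1 - f_true) * exp(-b * d_true))
  dwi <- signal_series(function(bv) s[match(bv, b)], b, "b-value")
  fit <- fit_ivim_simplified(dwi)
  d_hat <- fit$D$values[1, 1, 1]
  f_hat <- fit$f$values[1, 1, 1]
  # independent oracle: stats::lm on the high-b log signal
  hi <- b >= 200
  ol <- stats::lm(log(s[hi]) ~ b[hi])
  expect_equal(d_hat, -unname(coef(ol)[2]), tolerance = 1e-10)
  expect_equal(f_hat, 1 - exp(unname(coef(ol)[1])) / s[1], tolerance = 1e-10)
  # leverage-weighted contamination bound: the neglected pseudo-diffusion term
  # perturbs log S(b) by at most eps_b = (f/(1-f)) exp(-b (D* - D))
  bh <- b[hi]
  eps <- f_true / (1 - f_true) * exp(-bh * (dstar - d_true))
  sxx <- sum((bh - mean(bh))^2)
  w_int <- 1 / length(bh) + mean(bh) * (mean(bh) - bh) / sxx
  w_slp <- (bh - mean(bh)) / sxx
  expect_lt(abs(f_hat - f_true), (1 - f_true) * sum(abs(w_int) * eps) * 1.01)
  expect_lt(abs(d_hat - d_true), sum(abs(w_slp) * eps) * 1.01)
})

test_that("perfusion fractions are clamped to [0, 1] and counted", {
  b <- c(0, 200, 300, 400, 600, 800)
  d_true <- 1.0e-3
  # tissue-only decay but an S(0) below the extrapolated intercept -> f < 0
  vols <- lapply(b, function(bv) image_volume(array(exp(-bv * d_true), c(2, 2, 1))))
  vols[[1]]$values[] <- 0.97
  fit <- fit_ivim_simplified(acquisition_series(vols, "b-value", b))
  expect_true(all(fit$f$values == 0))
  expect_identical(attr(fit$f, "fit_report")$n_clamped_low, 4L)
})

test_that("the hypoxia score combines D and f pointwise", {
  d <- c(3, 3, 2)
  D <- parametric_map(array(1.2e-3, d), "D")
  f <- parametric_map(array(0.1, d), "f")
  # projection combine returns the D map itself
  hs_d <- compute_hypoxia_score(D, f, combine = function(D, f) D)
  expect_equal(hs_d$values, D$values)
  # constant inputs give the constant default score
  hs <- compute_hypoxia_score(D, f)
  expect_equal(unique(as.vector(hs$values)), hs_combine_default(1.2e-3, 0.1))
  # invalid voxels propagate
  fv <- f$values; fv[1, 1, 1] <- NaN
  f2 <- parametric_map(fv, "f")
  hs2 <- compute_hypoxia_score(D, f2)
  expect_false(hs2$valid[1, 1, 1])
  expect_true(is.nan(hs2$values[1, 1, 1]))
})

test_that("R2* fitting inverts noiseless decays and agrees with nlsLM", {
  te <- seq(4.92, 73.8, length.out = 12)
  r2s_true <- 30
  megre <- signal_series(function(te) 1000 * exp(-te / 1000 * r2s_true),
                         te, "echo-time")
  m <- fit_r2star(megre)
  expect_equal(unique(as.vector(m$values)), r2s_true, tolerance = 1e-6)
  # constant signal -> zero decay
  flat <- fit_r2star(signal_series(function(te) 400, te, "echo-time"))
  expect_true(all(flat$values == 0))
  expect_error(fit_r2star(signal_series(function(te) 1, te[1:2], "echo-time")),
               "three echoes")
  # two-solver agreement on noisy single-voxel decays
  skip_if_not_installed("minpack.lm")
  set.seed(3)
  for (i in 1:5) {
    s <- 1000 * exp(-te / 1000 * 25) + rnorm(12, 0, 10)
    vols <- lapply(s, function(x) image_volume(array(x, c(1, 1, 1))))
    mine <- fit_r2star(acquisition_series(vols, "echo-time", te))$values[1, 1, 1]
    oracle <- minpack.lm::nlsLM(
      s ~ s0 * exp(-te / 1000 * r2), start = list(s0 = max(s), r2 = 20),
      lower = c(0, 0), control = minpack.lm::nls.lm.control(ftol = 1e-14))
    expect_equal(mine, unname(coef(oracle)["r2"]), tolerance = 1e-5)
  }
})

test_that("flip-angle correction divides the actual by the nominal angle", {
  d <- c(4, 4, 2)
  k1 <- flip_angle_correction(image_volume(array(90, d)))
  expect_true(all(k1$values == 1))
  k09 <- flip_angle_correction(image_volume(array(81, d)))
  expect_true(all(k09$values == 0.9))
  neg <- flip_angle_correction(image_volume(array(c(-5, rep(45, 31)), d)))
  expect_true(is.nan(neg$values[1, 1, 1]))
  expect_equal(neg$values[2, 1, 1], 0.5)
})

test_that("VFA T1 fitting inverts the SPGR model and needs the right kappa", {
  alphas <- c(2, 5, 10, 15, 20, 30)
  tr <- 4.63; t1_true <- 1400
  vfa <- signal_series(function(a) spgr_signal(a, 1800, t1_true, tr),
                       alphas, "flip-angle", tr = tr)
  m <- fit_t1_vfa(vfa, kappa = 1)
  expect_equal(unique(as.vector(m$values)), t1_true, tolerance = 1e-6)
  # identity correction map leaves the fit unchanged
  ones <- image_volume(array(1, c(4, 4, 2)))
  expect_equal(fit_t1_vfa(vfa, kappa = ones)$values, m$values)
  # signals generated at kappa = 0.9 but fitted at kappa = 1 are biased;
  # refitting with the true kappa recovers T1
  vfa09 <- signal_series(function(a) spgr_signal(a, 1800, t1_true, tr, kappa = 0.9),
                         alphas, "flip-angle", tr = tr)
  biased <- fit_t1_vfa(vfa09, kappa = 1)
  expect_gt(abs(biased$values[1, 1, 1] - t1_true) / t1_true, 0.05)
  fixed <- fit_t1_vfa(vfa09, kappa = image_volume(array(0.9, c(4, 4, 2))))
  expect_equal(unique(as.vector(fixed$values)), t1_true, tolerance = 1e-6)
})

test_that("two-angle VFA equals the DESPOT1 closed form", {
  alphas <- c(5, 25); tr <- 4.63; t1_true <- 1100; m0 <- 1500
  s <- spgr_signal(alphas, m0, t1_true, tr)
  vfa <- signal_series(function(a) s[match(a, alphas)], alphas, "flip-angle",
                       tr = tr)
  m <- fit_t1_vfa(vfa, kappa = 1)
  a <- alphas * pi / 180
  e1 <- diff(s / sin(a)) / diff(s / tan(a))   # DESPOT1 closed form
  expect_equal(m$values[1, 1, 1], -tr / log(e1), tolerance = 1e-8)
})

test_that("coarse-grid B1 maps are resampled onto the VFA grid", {
  spec <- small_spec(b1_dim = c(16, 16, 6), b1_noise_sd = 0)
  truth <- suppressMessages(build_truth(spec))
  b1 <- qmrirep:::simulate_b1_map(truth, noise_scale = 0)
  expect_identical(dim(b1$values), c(16L, 16L, 6L))
  target <- image_volume(array(0, spec$dim), spacing = spec$spacing)
  kappa <- flip_angle_correction(b1, nominal = 90, target = target)
  expect_identical(dim(kappa$values), as.integer(spec$dim))
  # interior voxels reproduce the generative field to interpolation accuracy
  interior <- truth$regions$wg
  err <- abs(kappa$values - truth$gen$kappa)[interior]
  expect_lt(max(err), 0.01)
})

test_that("noise at SNR >= 20 leaves the median parameter bias below 2%", {
  spec <- small_spec(drift_sd = 0, jitter_mm = 0, jitter_deg = 0,
                     pz_dwi_noise_inflation = 1)
  st0 <- simulate_study(spec, seed = 8, noise_scale = 0, perturb = FALSE)
  ref <- fit_qmaps(st0$sessions[[1]])   # noiseless estimator target
  st <- simulate_study(spec, seed = 8, noise_scale = 1, perturb = FALSE)
  noisy <- fit_qmaps(st$sessions[[1]])
  wg <- st$truth$regions$wg
  for (q in c("ADC", "D", "f", "R2*", "T1")) {
    sel <- wg & ref[[q]]$valid & noisy[[q]]$valid
    bias <- stats::median((noisy[[q]]$values[sel] - ref[[q]]$values[sel]) /
                            ref[[q]]$values[sel])
    expect_lt(abs(bias), 0.02)
  }
})

test_that("fit_qmaps returns the full set of deterministic maps", {
  spec <- small_spec()
  st <- simulate_study(spec, seed = 12)
  maps <- fit_qmaps(st$sessions[[1]])
  expect_named(maps, c("ADC", "D", "f", "HS", "R2*", "T1", "T2w"))
  maps2 <- fit_qmaps(st$sessions[[1]])
  for (q in names(maps)) expect_identical(maps[[q]]$values, maps2[[q]]$values)
  # fitted maps satisfy their range invariants where valid
  expect_true(all(maps$f$values[maps$f$valid] >= 0 &
                    maps$f$values[maps$f$valid] <= 1))
  for (q in c("ADC", "D", "R2*", "T1")) {
    expect_true(all(maps[[q]]$values[maps[[q]]$valid] >= 0))
  }
})
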