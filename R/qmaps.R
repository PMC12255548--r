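#' Two-point apparent diffusion coefficient
#'
#' Linearised mono-exponential ADC from a pair of b-values (default 50 and
#' 800 s/mm^2, the pair in common clinical use):
#' `ADC = ln(S(b1) / S(b2)) / (b2 - b1)`. Voxels with a non-positive signal at
#' either b-value are invalid, as are the (noise-driven) voxels where the
#' estimate comes out negative; both are counted in the fit report.
#'
#' @param dwi An [acquisition_series()] of kind `"b-value"`.
#' @param b_pair The two b-values to use; both must be present in the series.
#' @return A [parametric_map()] of quantity `"ADC"` (mm^2/s), with a
#'   `fit_report` attribute (valid/invalid counts).
#' @export
fit_adc <- function(dwi, b_pair = c(50, 800)) {
  stopifnot(inherits(dwi, "acquisition_series"), dwi$axis_kind == "b-value")
  if (b_pair[1] == b_pair[2]) stop("the two b-values must differ", call. = FALSE)
  idx <- match(b_pair, dwi$axis_values)
  if (anyNA(idx)) {
    stop("b-value ", paste(b_pair[is.na(idx)], collapse = ", "),
         " s/mm^2 not present in the series", call. = FALSE)
  }
  s1 <- dwi$volumes[[idx[1]]]$values
  s2 <- dwi$volumes[[idx[2]]]$values
  ok <- is.finite(s1) & is.finite(s2) & s1 > 0 & s2 > 0
  adc <- array(NaN, dim(s1))
  adc[ok] <- log(s1[ok] / s2[ok]) / (b_pair[2] - b_pair[1])
  neg <- ok & !is.na(adc) & adc < 0
  adc[neg] <- NaN
  ref <- dwi$volumes[[1]]
  out <- parametric_map(adc, "ADC", ref$spacing, ref$origin, ref$orientation,
                        valid = ok & !neg)
  attr(out, "fit_report") <- list(n_valid = sum(ok & !neg),
                                  n_nonpositive_signal = sum(!ok),
                                  n_negative_estimate = sum(neg))
  out
}

#' Simplified IVIM fit (high-b mono-exponential)
#'
#' Intravoxel incoherent motion parameters under the simplifying assumption
#' that pseudo-diffusion contributes negligibly above `b_min` (default
#' 200 s/mm^2): an ordinary least-squares line through `ln S(b)` for
#' `b >= b_min` gives slope `-D` and intercept `c`, and the perfusion fraction
#' is referenced to the measured b = 0 signal, `f = 1 - exp(c) / S(0)`,
#' clamped to \[0, 1\] with the number of clamped voxels recorded.
#'
#' @param dwi An [acquisition_series()] of kind `"b-value"`; must contain a
#'   b = 0 volume and at least two b-values `>= b_min`.
#' @param b_min Threshold (s/mm^2) above which pseudo-diffusion is neglected.
#' @return A list with [parametric_map()]s `D` (mm^2/s) and `f`
#'   (dimensionless), each carrying a `fit_report` attribute.
#' @export
fit_ivim_simplified <- function(dwi, b_min = 200) {
  stopifnot(inherits(dwi, "acquisition_series"), dwi$axis_kind == "b-value")
  if (!0 %in% dwi$axis_values) {
    stop("simplified IVIM requires a b = 0 volume", call. = FALSE)
  }
  hi <- which(dwi$axis_values >= b_min)
  if (length(hi) < 2) {
    stop("need at least two b-values >= ", b_min, " s/mm^2", call. = FALSE)
  }
  s0 <- dwi$volumes[[match(0, dwi$axis_values)]]$values
  d <- dim(s0)
  Y <- matrix(vapply(dwi$volumes[hi], function(v) as.vector(v$values),
                     numeric(prod(d))), nrow = prod(d))
  b <- dwi$axis_values[hi]
  w <- (is.finite(Y) & Y > 0) * 1
  logY <- suppressWarnings(log(Y))
  logY[w == 0] <- 0
  fit <- ols_line_voxels(b, logY, w)
  ok <- fit$n >= 2 & is.finite(as.vector(s0)) & as.vector(s0) > 0 &
    is.finite(fit$slope)
  D <- -fit$slope
  f <- 1 - exp(fit$intercept) / as.vector(s0)
  neg_d <- ok & D < 0
  ok_d <- ok & !neg_d
  clamp_lo <- ok & f < 0
  clamp_hi <- ok & f > 1
  f <- pmin(pmax(f, 0), 1)
  dv <- array(NaN, d); dv[ok_d] <- D[ok_d]
  fv <- array(NaN, d); fv[ok] <- f[ok]
  ref <- dwi$volumes[[1]]
  map_d <- parametric_map(dv, "D", ref$spacing, ref$origin, ref$orientation,
                          valid = array(ok_d, d))
  map_f <- parametric_map(fv, "f", ref$spacing, ref$origin, ref$orientation,
                          valid = array(ok, d))
  attr(map_d, "fit_report") <- list(n_valid = sum(ok_d),
                                    n_negative_estimate = sum(neg_d),
                                    n_too_few_points = sum(fit$n < 2))
  attr(map_f, "fit_report") <- list(n_valid = sum(ok),
                                    n_clamped_low = sum(clamp_lo),
                                    n_clamped_high = sum(clamp_hi))
  list(D = map_d, f = map_f)
}

#' Hypoxia score from D and f
#'
#' Combines the diffusion coefficient (oxygen-consumption proxy) and the
#' perfusion fraction (oxygen-supply proxy) voxel-wise into a hypoxia score.
#' No rescaling or distribution matching is applied to D and f beforehand.
#' The combination is pluggable; the default [hs_combine_default()] is a
#' standardised contrast `f - D / s_D` and is an implementation default, not a
#' published formula.
#'
#' @param D,f Aligned [parametric_map()]s of quantities `"D"` and `"f"`.
#' @param combine `function(D_values, f_values)` applied voxel-wise.
#' @return A [parametric_map()] of quantity `"HS"` (dimensionless); invalid
#'   wherever either input is invalid.
#' @export
compute_hypoxia_score <- function(D, f, combine = hs_combine_default) {
  stopifnot(inherits(D, "parametric_map"), inherits(f, "parametric_map"))
  stop_if_unaligned(D, f, "D and f maps")
  valid <- D$valid & f$valid
  hs <- array(NaN, dim(D$values))
  hs[valid] <- combine(D$values[valid], f$values[valid])
  parametric_map(hs, "HS", D$spacing, D$origin, D$orientation,
                 valid = valid & is.finite(hs))
}

#' @rdname compute_hypoxia_score
#' @param D_values,f_values Numeric vectors of valid voxel values.
#' @param s_D Scale constant (mm^2/s) rendering D dimensionless. The default
#'   (0.02) keeps the standardised consumption term commensurate with typical
#'   perfusion fractions, so the score stays positive over physiological
#'   prostate D and f ranges (a requirement for percent-CV statistics).
#' @export
hs_combine_default <- function(D_values, f_values, s_D = 0.02) {
  f_values - D_values / s_D
}

#' Mono-exponential R2* fit
#'
#' Fits `S(TE) = S0 * exp(-TE * R2*)` to multi-echo gradient-echo data by
#' bounded nonlinear least squares (vectorised Levenberg-Marquardt,
#' relative-change tolerance 1e-8), initialised from the log-linear fit.
#' R2* is constrained non-negative. Echo times are in ms; R2* is returned in
#' 1/s.
#'
#' @param megre An [acquisition_series()] of kind `"echo-time"` with at least
#'   three echoes.
#' @return A [parametric_map()] of quantity `"R2*"` (1/s) with a `fit_report`
#'   attribute.
#' @export
fit_r2star <- function(megre) {
  stopifnot(inherits(megre, "acquisition_series"),
            megre$axis_kind == "echo-time")
  if (length(megre$axis_values) < 3) {
    stop("R2* fitting requires at least three echoes", call. = FALSE)
  }
  te_s <- megre$axis_values / 1000  # ms -> s
  Y <- series_matrix(megre)
  ok <- rowSums(!(is.finite(Y) & Y > 0)) == 0
  n <- nrow(Y)
  theta <- matrix(0, n, 2)
  if (any(ok)) {
    init <- ols_line_voxels(te_s, log(pmax(Y, .Machine$double.xmin)),
                            matrix(1, n, length(te_s)))
    theta[, 1] <- exp(pmin(init$intercept, 700))       # S0
    theta[, 2] <- pmax(-init$slope, 0)                 # R2* (1/s)
  }
  pj <- function(th) {
    E <- exp(-outer(th[, 2], te_s))
    list(pred = th[, 1] * E, J1 = E,
         J2 = -th[, 1] * E * matrix(te_s, n, length(te_s), byrow = TRUE))
  }
  fit <- lm_fit2(theta, pj, Y, lower = c(0, 0), upper = c(Inf, Inf))
  valid <- ok & fit$converged & is.finite(fit$theta[, 2])
  d <- dim(megre$volumes[[1]]$values)
  r2s <- array(NaN, d)
  r2s[valid] <- fit$theta[valid, 2]
  ref <- megre$volumes[[1]]
  out <- parametric_map(r2s, "R2*", ref$spacing, ref$origin, ref$orientation,
                        valid = array(valid, d))
  attr(out, "fit_report") <- list(n_valid = sum(valid),
                                  n_nonpositive_signal = sum(!ok),
                                  n_nonconverged = sum(ok & !fit$converged),
                                  iterations = fit$iterations)
  out
}

#' Flip-angle correction factor from a B1+ map
#'
#' The correction factor is the actual flip angle (the inline output of B1+
#' mapping) divided by the nominal applied angle (default 90 degrees). If a
#' target grid is supplied and differs from the B1 map grid, the factor map is
#' resampled onto it with trilinear interpolation.
#'
#' @param b1_actual An [image_volume()] of actual flip angles in degrees.
#' @param nominal Nominal flip angle in degrees (> 0).
#' @param target Optional `image_volume` defining the output grid (e.g. the
#'   VFA grid).
#' @return An `image_volume` of correction factors; non-positive actual angles
#'   become `NaN` (invalid).
#' @export
flip_angle_correction <- function(b1_actual, nominal = 90, target = NULL) {
  stopifnot(inherits(b1_actual, "image_volume"), nominal > 0)
  kappa <- b1_actual$values / nominal
  kappa[!is.finite(kappa) | b1_actual$values <= 0] <- NaN
  out <- image_volume(kappa, b1_actual$spacing, b1_actual$origin,
                      b1_actual$orientation)
  if (!is.null(target) && !volumes_aligned(out, target)) {
    out <- resample_to(out, target)
  }
  out
}

# Resample `volume` onto the grid of `target` by matching physical positions
# (shared orientation assumed), trilinear interpolation.
resample_to <- function(volume, target) {
  d <- dim(target$values)
  g <- index_grid(d)
  px <- target$origin[1] + g$i * target$spacing[1]
  py <- target$origin[2] + g$j * target$spacing[2]
  pz <- target$origin[3] + g$k * target$spacing[3]
  out <- trilinear_sample(volume$values,
                          (px - volume$origin[1]) / volume$spacing[1],
                          (py - volume$origin[2]) / volume$spacing[2],
                          (pz - volume$origin[3]) / volume$spacing[3])
  image_volume(array(out, d), target$spacing, target$origin,
               target$orientation)
}

#' Variable-flip-angle T1 fit with B1 correction
#'
#' Fits the SPGR steady-state model
#' `S(a) = M0 * sin(k a) * (1 - E1) / (1 - E1 * cos(k a))`, `E1 = exp(-TR/T1)`,
#' per voxel by nonlinear least squares on `(M0, E1)` initialised from the
#' DESPOT1 linearisation (`S/sin(k a)` vs `S/tan(k a)`, slope `E1`). The
#' applied flip angles are uniformly scaled by the per-voxel correction factor
#' `kappa`. Voxels whose fitted `E1` lies outside (0, 1) are invalid.
#'
#' @param vfa An [acquisition_series()] of kind `"flip-angle"` (degrees) with
#'   `repetition_time` in ms.
#' @param kappa Flip-angle correction: an aligned [image_volume()] or a single
#'   number (1 = no correction).
#' @return A [parametric_map()] of quantity `"T1"` (ms) with a `fit_report`
#'   attribute.
#' @export
fit_t1_vfa <- function(vfa, kappa = 1) {
  stopifnot(inherits(vfa, "acquisition_series"), vfa$axis_kind == "flip-angle")
  if (length(vfa$axis_values) < 2) {
    stop("T1 fitting requires at least two flip angles", call. = FALSE)
  }
  tr <- vfa$repetition_time
  d <- dim(vfa$volumes[[1]]$values)
  n <- prod(d)
  if (inherits(kappa, "image_volume")) {
    stop_if_unaligned(vfa$volumes[[1]], kappa, "VFA and kappa")
    kv <- as.vector(kappa$values)
  } else {
    kv <- rep(as.numeric(kappa), n)
  }
  Y <- series_matrix(vfa)
  a_eff <- outer(kv, vfa$axis_values * pi / 180)  # n x m, radians
  sin_a <- sin(a_eff); cos_a <- cos(a_eff)
  ok <- rowSums(!(is.finite(Y) & Y > 0)) == 0 & is.finite(kv) & kv > 0
  # DESPOT1 initialisation
  init <- ols_line_voxels(Y / tan(a_eff), Y / sin_a,
                          matrix(1, n, ncol(Y)))
  e1 <- init$slope
  bad_init <- !is.finite(e1) | e1 <= 0 | e1 >= 1
  e1[bad_init] <- exp(-tr / 1000)
  m0 <- init$intercept / (1 - e1)
  m0[!is.finite(m0) | m0 <= 0] <- rowMeans(Y)[!is.finite(m0) | m0 <= 0]
  eps <- 1e-12
  pj <- function(th) {
    den <- 1 - th[, 2] * cos_a
    pred <- th[, 1] * sin_a * (1 - th[, 2]) / den
    list(pred = pred,
         J1 = sin_a * (1 - th[, 2]) / den,
         J2 = th[, 1] * sin_a * (cos_a - 1) / den^2)
  }
  fit <- lm_fit2(cbind(m0, e1), pj, Y, lower = c(0, eps),
                 upper = c(Inf, 1 - eps))
  e1_hat <- fit$theta[, 2]
  in_range <- e1_hat > 1e-8 & e1_hat < 1 - 1e-8
  valid <- ok & fit$converged & in_range
  t1 <- array(NaN, d)
  t1[valid] <- -tr / log(e1_hat[valid])
  ref <- vfa$volumes[[1]]
  out <- parametric_map(t1, "T1", ref$spacing, ref$origin, ref$orientation,
                        valid = array(valid, d))
  attr(out, "fit_report") <- list(n_valid = sum(valid),
                                  n_nonpositive_signal = sum(!ok),
                                  n_e1_out_of_range = sum(ok & !in_range),
                                  n_nonconverged = sum(ok & !fit$converged),
                                  iterations = fit$iterations)
  out
}

#' Fit all parameter maps for one imaging session
#'
#' Convenience driver running the full map-fitting stage on one session of a
#' study: two-point ADC, simplified IVIM D and f, the hypoxia score,
#' mono-exponential R2*, and B1-corrected VFA T1. The T2w volume is passed
#' through as a `"T2w"` parametric map so that texture extraction can treat
#' all seven image types uniformly.
#'
#' @param session A list with elements `dwi`, `megre`, `vfa`
#'   ([acquisition_series()]), `b1` and `t2w` ([image_volume()]), as produced
#'   by [simulate_session()].
#' @param hs_combine Combination function for the hypoxia score.
#' @param adc_b_pair,ivim_b_min See [fit_adc()] and [fit_ivim_simplified()].
#' @return Named list of [parametric_map()]s:
#'   `ADC`, `D`, `f`, `HS`, `R2*`, `T1`, `T2w`.
#' @export
fit_qmaps <- function(session, hs_combine = hs_combine_default,
                      adc_b_pair = c(50, 800), ivim_b_min = 200) {
  adc <- fit_adc(session$dwi, b_pair = adc_b_pair)
  ivim <- fit_ivim_simplified(session$dwi, b_min = ivim_b_min)
  hs <- compute_hypoxia_score(ivim$D, ivim$f, combine = hs_combine)
  r2s <- fit_r2star(session$megre)
  kappa <- flip_angle_correction(session$b1, nominal = 90,
                                 target = session$vfa$volumes[[1]])
  t1 <- fit_t1_vfa(session$vfa, kappa = kappa)
  t2w <- parametric_map(session$t2w$values, "T2w", session$t2w$spacing,
                        session$t2w$origin, session$t2w$orientation)
  list(ADC = adc, D = ivim$D, f = ivim$f, HS = hs, `R2*` = r2s, T1 = t1,
       T2w = t2w)
}
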