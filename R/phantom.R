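#' Synthetic test-retest prostate phantom: specification
#'
#' Defines the geometry, ground-truth tissue values, acquisition protocol,
#' noise model and inter-session perturbations of the digital phantom used to
#' validate the repeatability pipeline. Defaults describe a small prostate-like
#' object: an ellipsoidal whole gland with a posterior peripheral-zone shell
#' and a spherical tumor inside the PZ, imaged twice with the full protocol
#' (9-b-value diffusion, 12-echo gradient echo, 6-angle VFA SPGR with a smooth
#' B1+ field, and a T2w volume), with Rician noise, optional PZ-specific
#' diffusion noise inflation (emulating susceptibility effects near the
#' rectum), and session-2 rigid jitter plus multiplicative parameter drift.
#'
#' Ground-truth tissue values are configuration defaults drawn from typical
#' 3 T prostate literature ranges; they are not fitted to any specific cohort.
#'
#' @param dim Grid shape (voxels).
#' @param spacing Voxel size in mm.
#' @param wg_semiaxes Whole-gland ellipsoid semi-axes in mm (x, y, z).
#' @param pz_shell_frac PZ shell thickness as a fraction of the normalised
#'   ellipsoid radius; the PZ is the posterior (y > centre) part of the shell.
#' @param tumor_offset Tumor sphere centre offset from the gland centre (mm).
#' @param tumor_radius Tumor sphere radius in mm (0 = no lesion).
#' @param values Named list of per-region ground-truth values; each element is
#'   a vector with entries `pz`, `npz`, `tumor`, `background`. Parameters:
#'   `D` (mm^2/s), `f`, `r2star` (1/s), `t1` (ms), `s0_dwi`, `s0_megre`,
#'   `m0_vfa`, `t2w` (arbitrary signal units).
#' @param dstar_ratio Pseudo-diffusion coefficient as a multiple of D.
#' @param b_values,echo_times,flip_angles,tr Acquisition axes: b (s/mm^2),
#'   TE (ms), nominal flip angles (degrees), TR (ms).
#' @param b1_coef B1+ field polynomial coefficients `(const, lin_x, quad)`:
#'   `kappa = const + lin_x * u + quad * (u^2 + v^2)` with `u, v` the
#'   normalised in-plane offsets from the grid centre.
#' @param b1_dim,b1_noise_sd B1 map grid shape (`NULL` = the acquisition
#'   grid; a coarser grid emulates low-resolution B1 mapping and is resampled
#'   during fitting) and Gaussian noise sd on the actual flip angle (degrees).
#' @param sigma Named complex-noise standard deviations per series
#'   (`dwi`, `megre`, `vfa`, `t2w`), in signal units.
#' @param pz_dwi_noise_inflation Multiplier on the diffusion-series noise sd
#'   inside the PZ (1 = homogeneous noise).
#' @param jitter_mm,jitter_deg Magnitudes of the session-2 rigid jitter
#'   (translation in mm, rotation in degrees); the direction is drawn at
#'   simulation time.
#' @param drift_sd Standard deviation of the session-2 multiplicative
#'   parameter drift (fraction).
#' @param subject_sd Standard deviation of the per-subject multiplicative
#'   variation of tissue values, used by [simulate_cohort()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(56, 56, 8),
                         spacing = c(1, 1, 3),
                         wg_semiaxes = c(16, 13, 9),
                         pz_shell_frac = 0.4,
                         tumor_offset = c(0, 6, 0),
                         tumor_radius = 4,
                         values = list(
                           D       = c(pz = 1.55e-3, npz = 1.25e-3,
                                       tumor = 0.80e-3, background = 1.8e-3),
                           f       = c(pz = 0.10, npz = 0.14,
                                       tumor = 0.07, background = 0.05),
                           r2star  = c(pz = 25, npz = 30,
                                       tumor = 40, background = 35),
                           t1      = c(pz = 1600, npz = 1400,
                                       tumor = 1300, background = 1000),
                           s0_dwi  = c(pz = 1000, npz = 800,
                                       tumor = 900, background = 400),
                           s0_megre = c(pz = 1000, npz = 900,
                                        tumor = 950, background = 400),
                           m0_vfa  = c(pz = 2000, npz = 1800,
                                       tumor = 1900, background = 800),
                           t2w     = c(pz = 600, npz = 400,
                                       tumor = 300, background = 150)),
                         dstar_ratio = 10,
                         b_values = c(0, 20, 50, 100, 200, 300, 400, 600, 800),
                         echo_times = seq(4.92, 73.8, length.out = 12),
                         flip_angles = c(2, 5, 10, 15, 20, 30),
                         tr = 4.63,
                         b1_coef = c(const = 0.95, lin_x = 0.05, quad = -0.08),
                         b1_dim = NULL,
                         b1_noise_sd = 0.5,
                         sigma = c(dwi = 20, megre = 15, vfa = 1.5, t2w = 15),
                         pz_dwi_noise_inflation = 2,
                         jitter_mm = 0.8,
                         jitter_deg = 0.7,
                         drift_sd = 0.02,
                         subject_sd = 0.05) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$dim) == 3, all(spec$dim >= 4),
            all(spec$spacing > 0), all(spec$wg_semiaxes > 0),
            spec$tumor_radius >= 0, all(spec$sigma >= 0),
            spec$pz_dwi_noise_inflation >= 1, spec$dstar_ratio > 1,
            spec$drift_sd >= 0, spec$subject_sd >= 0)
  for (nm in names(spec$values)) {
    v <- spec$values[[nm]]
    if (!all(c("pz", "npz", "tumor", "background") %in% names(v))) {
      stop("values$", nm, " must name pz, npz, tumor, background", call. = FALSE)
    }
    if (any(v <= 0)) stop("values$", nm, " must be positive", call. = FALSE)
  }
  if (any(spec$values$f >= 1)) stop("f values must lie in (0, 1)", call. = FALSE)
  # tumor sphere must sit fully inside the WG ellipsoid
  if (spec$tumor_radius > 0) {
    ctr <- spec$tumor_offset
    a <- spec$wg_semiaxes
    # worst case along each principal direction from the tumor centre
    reach <- sqrt(sum((ctr / a)^2)) + spec$tumor_radius / min(a)
    if (reach > 1) {
      stop("tumor sphere escapes the whole-gland ellipsoid", call. = FALSE)
    }
  }
  invisible(spec)
}

# Physical voxel-centre coordinates relative to the grid centre (mm).
phantom_coords <- function(spec) {
  g <- index_grid(spec$dim)
  ctr <- (spec$dim - 1) / 2 * spec$spacing
  list(x = g$i * spec$spacing[1] - ctr[1],
       y = g$j * spec$spacing[2] - ctr[2],
       z = g$k * spec$spacing[3] - ctr[3])
}

#' Build the phantom ground truth
#'
#' Constructs the region masks (via the same delineation rules the analysis
#' uses: 1 mm whole-gland erosion, PZ subtraction, Yen thresholding of the
#' synthetic tumor probability map), the piecewise-constant generative tissue
#' maps, the smooth B1+ correction field, and the derived ground-truth
#' parametric maps (ADC and HS are closed-form functions of D, f and D*).
#'
#' @param spec A [phantom_spec()].
#' @param value_scale Optional named vector of multiplicative factors applied
#'   to the tissue values of individual parameters (used for per-subject
#'   variation); names must match `names(spec$values)`.
#' @return A list of class `phantom_truth` with elements `maps` (ground-truth
#'   [parametric_map()]s `ADC`, `D`, `f`, `HS`, `R2*`, `T1`, `T2w`), `gen`
#'   (generative arrays incl. signal amplitudes and `kappa`), `regions`
#'   (a [region_set()]), `masks` (raw anatomical masks), `tumor_prob`
#'   (an [image_volume()]), and `spec`.
#' @export
build_truth <- function(spec, value_scale = NULL) {
  validate_phantom_spec(spec)
  d <- spec$dim
  co <- phantom_coords(spec)
  a <- spec$wg_semiaxes
  rho <- sqrt((co$x / a[1])^2 + (co$y / a[2])^2 + (co$z / a[3])^2)
  wg_raw <- array(rho <= 1, d)
  pz_raw <- wg_raw & array(rho >= 1 - spec$pz_shell_frac & co$y > 0, d)
  tum_d2 <- (co$x - spec$tumor_offset[1])^2 + (co$y - spec$tumor_offset[2])^2 +
    (co$z - spec$tumor_offset[3])^2
  tumor_raw <- if (spec$tumor_radius > 0) {
    array(tum_d2 <= spec$tumor_radius^2, d)
  } else {
    array(FALSE, d)
  }
  prob <- if (spec$tumor_radius > 0) {
    w <- spec$tumor_radius / 1.8
    array(0.95 * exp(-tum_d2 / (2 * w^2)), d)
  } else {
    array(0, d)
  }
  regions <- derive_regions(wg_raw, pz_raw,
                            tumor_prob = if (spec$tumor_radius > 0) prob,
                            spacing = spec$spacing, erosion_mm = 1)
  vals <- spec$values
  if (!is.null(value_scale)) {
    for (nm in names(value_scale)) {
      vals[[nm]] <- vals[[nm]] * value_scale[[nm]]
    }
  }
  paint <- function(v) {
    out <- array(v[["background"]], d)
    out[wg_raw & !pz_raw] <- v[["npz"]]
    out[pz_raw] <- v[["pz"]]
    out[tumor_raw] <- v[["tumor"]]
    out
  }
  gen <- lapply(vals, paint)
  gen$f <- pmin(gen$f, 0.98)
  gen$kappa <- b1_field(spec)
  gen$dstar <- spec$dstar_ratio * gen$D
  # closed-form ADC implied by the two-compartment diffusion model at the
  # clinical b-pair (S0 cancels)
  sb <- function(b) gen$f * exp(-b * gen$dstar) + (1 - gen$f) * exp(-b * gen$D)
  adc <- log(sb(50) / sb(800)) / (800 - 50)
  hs <- hs_combine_default(gen$D, gen$f)
  pm <- function(x, q) parametric_map(x, q, spacing = spec$spacing)
  maps <- list(ADC = pm(adc, "ADC"), D = pm(gen$D, "D"), f = pm(gen$f, "f"),
               HS = pm(hs, "HS"), `R2*` = pm(gen$r2star, "R2*"),
               T1 = pm(gen$t1, "T1"), T2w = pm(gen$t2w, "T2w"))
  structure(
    list(maps = maps, gen = gen, regions = regions,
         masks = list(wg = wg_raw, pz = pz_raw, tumor = tumor_raw),
         tumor_prob = image_volume(prob, spec$spacing), spec = spec),
    class = "phantom_truth"
  )
}

# Smooth multiplicative B1+ (flip-angle correction) field on the main grid.
b1_field <- function(spec) {
  co <- phantom_coords(spec)
  half <- spec$dim[1:2] * spec$spacing[1:2] / 2
  u <- co$x / half[1]; v <- co$y / half[2]
  k <- spec$b1_coef[["const"]] + spec$b1_coef[["lin_x"]] * u +
    spec$b1_coef[["quad"]] * (u^2 + v^2)
  array(k, spec$dim)
}

# Rician magnitude: |signal + complex Gaussian noise| with per-voxel sd.
rician <- function(signal, sd) {
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sd))^2 + stats::rnorm(n, 0, sd)^2)
}

#' Forward-simulate one imaging session
#'
#' Generates the full acquisition set of one test-retest session from the
#' phantom ground truth, using the forward signal models
#' \itemize{
#'   \item diffusion: `S(b) = S0 (f exp(-b D*) + (1 - f) exp(-b D))`,
#'   \item multi-echo gradient echo: `S(TE) = S0 exp(-TE R2*)`,
#'   \item SPGR: `S(a) = M0 sin(k a) (1 - E1) / (1 - E1 cos(k a))`,
#'     `E1 = exp(-TR/T1)`, with the B1+ factor `k` scaling the nominal angle.
#' }
#' Noise is Rician (magnitude of signal plus complex Gaussian, per-channel sd
#' `sigma`), applied independently per volume; the diffusion-series sd is
#' inflated inside the PZ by `spec$pz_dwi_noise_inflation`. Session 2
#' additionally applies a rigid jitter (resampled back onto the reference
#' grid, emulating residual registration error) and a multiplicative
#' parameter drift; both are drawn from the current RNG state, so wrap calls
#' in `set.seed()` (or use [simulate_study()]) for reproducibility.
#'
#' @param truth A `phantom_truth` from [build_truth()].
#' @param session Session index: 1 (baseline; no jitter, no drift) or 2.
#' @param noise_scale Global multiplier on all noise sds (0 = noiseless).
#' @param perturb Apply session-2 jitter and drift? Set `FALSE` for
#'   noiseless closed-loop checks.
#' @param series Which series to generate (subset of
#'   `c("dwi", "megre", "vfa", "b1", "t2w")`); restricting the set speeds up
#'   simulations that only exercise one fitting path.
#' @return A list with the requested elements among `dwi`, `megre`, `vfa`
#'   ([acquisition_series()]), `b1`, `t2w` ([image_volume()]).
#' @export
simulate_session <- function(truth, session = 1, noise_scale = 1,
                             perturb = TRUE,
                             series = c("dwi", "megre", "vfa", "b1", "t2w")) {
  stopifnot(inherits(truth, "phantom_truth"), session %in% 1:2,
            noise_scale >= 0)
  series <- match.arg(series, several.ok = TRUE)
  spec <- truth$spec
  d <- spec$dim
  gen <- truth$gen
  jitter <- NULL
  if (session == 2 && perturb) {
    drift <- function() 1 + stats::rnorm(1, 0, spec$drift_sd)
    for (nm in c("D", "f", "r2star", "t1", "s0_dwi", "s0_megre", "m0_vfa",
                 "t2w")) {
      gen[[nm]] <- gen[[nm]] * drift()
    }
    gen$f <- pmin(gen$f, 0.98)
    gen$dstar <- spec$dstar_ratio * gen$D
    tdir <- stats::rnorm(3); tdir <- tdir / sqrt(sum(tdir^2))
    rdir <- stats::rnorm(3); rdir <- rdir / sqrt(sum(rdir^2))
    jitter <- list(t = tdir * spec$jitter_mm, r = rdir * spec$jitter_deg)
  }
  deliver <- function(noiseless, sd) {
    if (!is.null(jitter)) {
      noiseless <- apply_rigid_jitter(
        image_volume(noiseless, spec$spacing),
        translation_mm = jitter$t, rotation_deg = jitter$r)$values
    }
    out <- if (noise_scale == 0 || all(sd == 0)) {
      noiseless
    } else {
      array(rician(as.vector(noiseless), rep(as.vector(sd) * noise_scale,
                                             length.out = length(noiseless))),
            d)
    }
    image_volume(out, spec$spacing)
  }
  out <- list()
  if ("dwi" %in% series) {
    sd_dwi <- array(spec$sigma[["dwi"]], d)
    sd_dwi[truth$masks$pz] <- sd_dwi[truth$masks$pz] *
      spec$pz_dwi_noise_inflation
    vols <- lapply(spec$b_values, function(b) {
      s <- gen$s0_dwi * (gen$f * exp(-b * gen$dstar) +
                           (1 - gen$f) * exp(-b * gen$D))
      deliver(s, sd_dwi)
    })
    out$dwi <- acquisition_series(vols, "b-value", spec$b_values)
  }
  if ("megre" %in% series) {
    vols <- lapply(spec$echo_times, function(te) {
      deliver(gen$s0_megre * exp(-te / 1000 * gen$r2star),
              spec$sigma[["megre"]])
    })
    out$megre <- acquisition_series(vols, "echo-time", spec$echo_times)
  }
  if ("vfa" %in% series) {
    e1 <- exp(-spec$tr / gen$t1)
    vols <- lapply(spec$flip_angles, function(alpha) {
      aa <- gen$kappa * alpha * pi / 180
      deliver(gen$m0_vfa * sin(aa) * (1 - e1) / (1 - e1 * cos(aa)),
              spec$sigma[["vfa"]])
    })
    out$vfa <- acquisition_series(vols, "flip-angle", spec$flip_angles,
                                  repetition_time = spec$tr)
  }
  if ("b1" %in% series) {
    out$b1 <- simulate_b1_map(truth, noise_scale)
  }
  if ("t2w" %in% series) {
    out$t2w <- deliver(gen$t2w, spec$sigma[["t2w"]])
  }
  out
}

# Actual-flip-angle map on its own (coarser) grid, in degrees. The B1+ field
# is a scanner property and is not jittered between sessions.
simulate_b1_map <- function(truth, noise_scale = 1) {
  spec <- truth$spec
  bd <- if (is.null(spec$b1_dim)) spec$dim else spec$b1_dim
  fov <- spec$dim * spec$spacing
  bsp <- fov / bd
  g <- index_grid(bd)
  ctr <- (bd - 1) / 2 * bsp
  u <- (g$i * bsp[1] - ctr[1]) / (fov[1] / 2)
  v <- (g$j * bsp[2] - ctr[2]) / (fov[2] / 2)
  k <- spec$b1_coef[["const"]] + spec$b1_coef[["lin_x"]] * u +
    spec$b1_coef[["quad"]] * (u^2 + v^2)
  deg <- k * 90
  if (noise_scale > 0 && spec$b1_noise_sd > 0) {
    deg <- deg + stats::rnorm(length(deg), 0, spec$b1_noise_sd * noise_scale)
  }
  # align grids: both cover the same field of view, corner at the same corner
  origin <- (bsp - spec$spacing) / 2
  image_volume(array(deg, bd), spacing = bsp, origin = origin)
}

#' Simulate a complete test-retest study for one subject
#'
#' Builds the ground truth and both imaging sessions under a fixed seed:
#' session 1 is the baseline, session 2 differs only through a new noise
#' realisation, the specified rigid jitter, and the specified parameter drift.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; fixes the study bit-reproducibly.
#' @inheritParams simulate_session
#' @return A list of class `synthetic_study`: `truth`, `sessions` (list of
#'   two), and `spec`.
#' @export
simulate_study <- function(spec = phantom_spec(), seed = 1, noise_scale = 1,
                           perturb = TRUE,
                           series = c("dwi", "megre", "vfa", "b1", "t2w")) {
  set.seed(seed)
  truth <- build_truth(spec)
  s1 <- simulate_session(truth, 1, noise_scale, perturb, series)
  s2 <- simulate_session(truth, 2, noise_scale, perturb, series)
  structure(list(truth = truth, sessions = list(s1, s2), spec = spec),
            class = "synthetic_study")
}

#' Simulate a test-retest cohort
#'
#' Generates a cohort of independent subjects (patients carry the tumor of the
#' spec; volunteers are simulated without a lesion), each with its own
#' per-subject multiplicative variation of the tissue values
#' (sd `spec$subject_sd`) and its own test-retest study.
#'
#' @param n_patients,n_volunteers Cohort composition.
#' @inheritParams simulate_study
#' @return A tibble with one row per subject: `subject`, `type`
#'   (`"patient"`/`"volunteer"`) and a `study` list-column of
#'   `synthetic_study` objects.
#' @export
simulate_cohort <- function(n_patients = 10, n_volunteers = 6,
                            spec = phantom_spec(), seed = 1, noise_scale = 1,
                            perturb = TRUE,
                            series = c("dwi", "megre", "vfa", "b1", "t2w")) {
  set.seed(seed)
  type <- c(rep("patient", n_patients), rep("volunteer", n_volunteers))
  vol_spec <- spec
  vol_spec$tumor_radius <- 0
  studies <- lapply(seq_along(type), function(s) {
    scale <- stats::setNames(
      1 + stats::rnorm(length(spec$values), 0, spec$subject_sd),
      names(spec$values))
    this_spec <- if (type[s] == "patient") spec else vol_spec
    truth <- suppressMessages(build_truth(this_spec, value_scale = scale))
    s1 <- simulate_session(truth, 1, noise_scale, perturb, series)
    s2 <- simulate_session(truth, 2, noise_scale, perturb, series)
    structure(list(truth = truth, sessions = list(s1, s2), spec = this_spec),
              class = "synthetic_study")
  })
  tibble::tibble(subject = seq_along(type), type = type, study = studies)
}

#' Expected %RC of a directly measured quantity
#'
#' Analytic oracle for the repeatability pipeline: a quantity measured twice
#' per voxel with i.i.d. additive noise of sd `sigma` about mean `mu`
#' (Gaussian regime, SNR of roughly 5 or more) has large-sample expected
#' repeatability coefficient `2.77 * 100 * sigma / mu`.
#'
#' @param sigma Noise standard deviation (>= 0).
#' @param mu Mean signal (> 0).
#' @return Expected %RC (percent).
#' @export
predict_rc_direct <- function(sigma, mu) {
  if (any(mu <= 0)) stop("mu must be positive", call. = FALSE)
  stopifnot(all(sigma >= 0))
  2.77 * 100 * sigma / mu
}
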