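---
title: "Methods: test-retest repeatability of prostate qMRI and texture features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: test-retest repeatability of prostate qMRI and texture features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

qmrirep estimates how repeatable quantitative MRI (qMRI) parameters and
voxel-wise radiomic texture features are between two imaging sessions of the
same subject, and whether that repeatability depends on where in the prostate
it is measured. The headline statistic is the QIBA-style repeatability
coefficient, %RC: the smallest percentage change between two scans that can be
attributed to a real effect rather than measurement noise. A longitudinal
study that wants to call a 20% drop in tumor ADC "response" needs to know
whether the %RC of tumor ADC is 10% or 40%.

This vignette documents the models, the statistical definitions, the synthetic
test-retest phantom, and the numerical and design choices behind the package.

## The repeatability statistics

For a quantity measured twice under identical conditions, the percent
coefficient of variation of the pair is

$$\%CV = 100 \cdot \frac{s}{\bar x},$$

with $s$ the sample standard deviation ($n-1$ denominator, so for two repeats
$s = |x_1 - x_2|/\sqrt 2$) and $\bar x$ the mean. The within-subject %CV is
the root mean square of %CV values — across subjects in ROI mode (one value
per cohort), across a region's voxels in voxel mode (one value per subject) —
and the repeatability coefficient is

$$\%RC = 2.77 \times \%wCV,$$

where $2.77 = 1.96\sqrt 2$ (rounded to two decimals) is the 95% bound on the
difference of two independent, identically distributed measurements.
`repeatability_coefficient()` implements the multiplication exactly; the
invariant `rc == 2.77 * wcv` holds for every record the pipeline produces.

Two analysis modes mirror how such studies are read:

* **ROI mode** — the measurement is the *median* of a map over a region (whole
  gland WG, peripheral zone PZ, non-peripheral zone nPZ, tumor, benign);
  %CV is computed per subject from the two session medians and aggregated
  across subjects (`roi_repeatability()`).
* **Voxel mode** — %CV is computed at every voxel from its two session
  values and aggregated over the region's voxels into one %wCV per subject;
  the cohort summary reports the median and range of the per-subject %RCs
  (`voxel_repeatability()`).

The %CV is undefined around zero, so voxels with a non-positive value in
either session (or a non-positive mean) are excluded and counted, and region
medians that come out non-positive yield missing records rather than
nonsense. A practical consequence worth knowing: a quantity whose values
approach zero inside a region (the default hypoxia score in the PZ, for
instance) will show an enormous and essentially meaningless %RC there —
the statistic, not the pipeline, is the limitation.

### Dependency testing and classification

Whether repeatability depends on anatomical zone (PZ vs nPZ, all subjects) or
tissue type (tumor vs benign, patients only) is tested with a two-tailed
paired t test across subjects at $\alpha = 0.05$, pairing per-subject %CV
(ROI mode) or per-subject %wCV (voxel mode). Subjects missing either member
of a pair are dropped pairwise with a logged count; fewer than three complete
pairs makes a contrast *untestable* rather than silently non-significant. A
degenerate pair set (zero variance of a nonzero mean difference) is reported
significant at the numerical floor and flagged, since its direction is
unambiguous but its p value is not meaningful. The two significance flags map
to the four categories *both* / *tissue only* / *zone only* / *neither*
(`classify_dependency()`), which decide whether one repeatability threshold
suffices for the whole gland. No multiple-testing correction enters this
classification — each of the 413 features is tested at its own
$\alpha = 0.05$ — but `dependency_table()` also emits Benjamini–Hochberg
adjusted p values as a transparency column.

### Feature ranking

`rank_features()` summarises each feature by one %RC: the WG value for
category *neither*, otherwise the *largest* %RC over the regions implied by
its category (PZ/nPZ, tumor/benign, or all four). Voxel mode uses the median
per-subject %RC. Features are sorted ascending and the top k (default 50)
returned; ties break lexicographically by (source image, class, name) so
rankings are deterministic.

## Parametric map fitting

Six maps are fitted per session, plus the T2w image carried through so texture
extraction treats all seven image types uniformly.

* **ADC** — linearised mono-exponential on the clinical b-pair,
  $ADC = \ln(S_{50}/S_{800})/750$. Closed form, no iteration.
* **Simplified IVIM** — assuming pseudo-diffusion contributes negligibly
  above $b = 200\,$s/mm², an ordinary least-squares line through $\ln S(b)$
  for $b \ge 200$ gives slope $-D$; the perfusion fraction is referenced to
  the measured $b=0$ volume, $f = 1 - e^{c}/S(0)$, clamped to $[0,1]$ with
  clamp counts recorded. Equal weights are used on the log scale (the
  simplest deterministic choice); weighting is a recorded alternative, not a
  default.
* **Hypoxia score** — a pluggable voxel-wise combination of D (consumption
  proxy) and f (supply proxy), with no rescaling or distribution matching of
  the inputs. The default, `hs_combine_default()`, is the standardised
  contrast $f - D/s_D$ with $s_D = 0.02\,$mm²/s. Both the form and the scale
  constant are implementation defaults, clearly flagged as such: the
  originating model's exact formula is not public in a form this package can
  cite, and $s_D$ was chosen once so the score stays positive over
  physiological prostate D and f ranges — a precondition for percent-CV
  statistics (see above).
* **R2\*** — bounded nonlinear least squares of $S(TE) = S_0 e^{-TE\,R2^*}$
  over 12 echoes, initialised from the log-linear fit, $R2^* \ge 0$.
* **B1⁺ correction** — $\kappa$ = actual flip angle (the inline output of B1
  mapping) divided by the nominal 90°, resampled onto the VFA grid when the
  B1 map is coarser.
* **VFA T1** — nonlinear least squares of the SPGR steady state
  $S(\alpha) = M_0 \sin(\kappa\alpha)(1 - E_1)/(1 - E_1\cos(\kappa\alpha))$,
  $E_1 = e^{-TR/T1}$, with nominal angles uniformly scaled by $\kappa$,
  initialised from the DESPOT1 linearisation ($S/\sin$ vs $S/\tan$, slope
  $E_1$). Voxels with fitted $E_1 \notin (0,1)$ are invalid.

The iterative fits share a vectorised two-parameter Levenberg–Marquardt core
(`lm_fit2`): both models have exactly two free parameters per voxel, so the
damped normal equations are 2×2 and solved in closed form for every voxel
simultaneously, each voxel carrying its own damping factor. Convergence is a
relative parameter change below $10^{-8}$; non-converged voxels are invalid
and counted. All fits are deterministic — there is no random initialisation
anywhere — and the noiseless phantom is recovered exactly (ADC, R2*, T1 to
well under $10^{-6}$ relative; see below for D and f). Cross-checks against
`minpack.lm::nlsLM` on single voxels are part of the test suite.

Invalid voxels carry `NaN` in the map values, with a parallel logical `valid`
grid as the authoritative record; every downstream statistic honours it.

### Why D and f are *not* recovered exactly

The simplified IVIM fit deliberately ignores the pseudo-diffusion compartment
above $b = 200$. With the phantom's $D^* = 10D$, the neglected term perturbs
$\ln S(b)$ by $\varepsilon_b = \frac{f}{1-f}e^{-b(D^*-D)}$, which is small
but nonzero at $b = 200$ (about 1% of log-signal for typical tissue). The
intercept of the high-b line is extrapolated from a mean b of 460 down to 0,
which *amplifies* that contamination: the resulting error bound is the
leverage-weighted sum $\sum_i |w_i|\,\varepsilon_{b_i}$ over the high-b
design, with $w_i$ the intercept (for f) or slope (for D) hat weights. For
f = 0.10, D = 1.2×10⁻³ mm²/s this works out to |Δf| ≈ 0.011 and ΔD/D ≈ 1.5% —
an inherent property of the simplified estimator, not a solver error. The
tests assert recovery to within this analytic bound, and the phantom's
ground-truth ADC is likewise *defined* through the two-compartment forward
model at b = 50/800 so that the ADC path closes exactly.

## Texture-feature maps

Preprocessing follows the standard radiomics chain: every image is resampled
to 1 mm isotropic resolution (trilinear; nearest-neighbour for masks),
z-score normalised with a scale factor of 100 and clipped to ±3 standard
deviations, so gray values span −300..300; discretisation uses a fixed bin
width of 20 anchored at the volume-global minimum, which keeps labels
comparable across sliding windows (a window-local anchor would make the same
tissue pattern produce different labels in different windows).

Features are extracted per voxel from an in-plane 5×5 mm window centred on
it, per slice. Four matrix classes with 59 features in total — GLCM (24),
GLRLM (16), GLDM (14), NGTDM (5), identifiers following the IBSI-compliant
naming — are evaluated per window, so a session yields 7 × 59 = 413 feature
maps. Choices the literature leaves open are fixed as follows:

* GLCM/GLRLM: distance 1, symmetric matrices, features computed per in-plane
  direction (0°, 45°, 90°, 135°) and averaged. Gray levels that occur in no
  pair of a given direction are dropped from that direction's marginals
  before feature evaluation.
* Edge voxels use window *cropping*, never padding — no intensities are
  invented; the feature is computed on the available sub-window.
* Degenerate single-level windows: correlation-type features are 1,
  difference-type features 0, NGTDM coarseness takes the customary 10⁶ cap;
  such windows are counted in the extraction report.
* GLDM: dependence is the count of 8-neighbours equal to the centre
  (α = 0), entering the formulas as $j = d + 1$.

The hot loop is compiled (Rcpp); a pure-R implementation of every matrix
builder and feature is retained in the package and the two paths are
cross-checked against each other — and against brute-force pair/run/
dependence/difference enumeration oracles — in the test suite. Feature maps
are stored compactly as a (masked voxels × 59) matrix per source image;
`as_feature_volume()` materialises any single map on the full grid.

## The synthetic test-retest phantom

No patient data ship with (or are reproducible by) this package; the phantom
exists so that every pipeline stage is testable end-to-end. It emulates:

* **Geometry** — an ellipsoidal whole gland (default semi-axes 16×13×9 mm) on
  a 56×56×8 grid at 1×1×3 mm; the PZ as the posterior outer shell of the
  ellipsoid; a spherical tumor (radius 4 mm) inside the gland. Region masks
  are *derived* through the same rules the analysis uses on real data: 1 mm
  3D erosion of the WG, nPZ = WG − PZ, and Yen thresholding of a smooth
  synthetic tumor-probability bump (so the segmentation path is exercised,
  imperfections included).
* **Acquisitions** — the full protocol via the forward signal models above:
  9 b-values (0–800 s/mm²), 12 echoes (4.92–73.8 ms), 6 flip angles
  (2/5/10/15/20/30° at TR 4.63 ms) under a smooth low-order-polynomial B1⁺
  field, and a T2w volume.
* **Noise** — Rician (magnitude of signal plus complex Gaussian), applied
  independently per volume. The diffusion-series noise sd is inflated inside
  the PZ (default 2×) to emulate susceptibility effects near the rectum —
  the mechanism behind zone-dependent repeatability.
* **Test-retest structure** — session 2 differs from session 1 only through
  a new noise realisation, a small rigid jitter (default 0.8 mm / 0.7°,
  random direction, resampled back onto the reference grid — a residual
  registration error), and a multiplicative per-parameter drift (default sd
  2%, day-to-day biological variation). Cohorts add a per-subject
  multiplicative variation of tissue values (sd 5%); volunteers are simulated
  without a lesion, so tissue contrasts automatically use patients only.

Ground-truth tissue values (e.g. benign PZ D = 1.55×10⁻³ mm²/s, tumor
0.80×10⁻³; T1 1300–1600 ms; R2* 25–40 s⁻¹) are configuration defaults chosen
once from typical 3 T prostate literature ranges — they are not calibrated to
any cohort, and the package makes no claim of reproducing any study's
specific %RC values. Noise sds (default DWI 20, MEGRE 15, VFA 1.5, T2w 15
signal units) put voxel SNR in the 10–50 range across the series, which
yields voxel-mode ADC %RCs of around 30% — the order of magnitude the field
reports.

What the phantom does **not** emulate: susceptibility-induced geometric
distortion, eddy currents, motion between b-values/echoes/angles, deformable
anatomy, bias fields (no N4 correction is needed or applied), real
segmentation-model behaviour, or realistic tissue heterogeneity
(tissue values are piecewise constant). Green tests therefore demonstrate
that the *estimators and statistics* are correct under their stated
assumptions, not that any particular clinical %RC value is right.

A fixed seed makes a study bit-reproducible. Everything random —
noise, jitter directions, drift, subject variation — flows from the single
seed given to `simulate_study()` / `simulate_cohort()`.

## Numerical choices and problem sizes

* Yen thresholding uses 256 histogram bins over the masked min–max range
  (the algorithm's source names no binning; 256 matches common
  implementations) and is restricted to the eroded gland — a conservative
  choice recorded here, and verified against an exhaustive criterion sweep on
  small instances. A constant probability map yields an empty tumor mask
  with a warning.
* Erosion uses a discretised ball: an offset belongs to the structuring
  element iff its centre distance in mm is at most the radius; voxels outside
  the grid count as background.
* The zone-effect power check runs 20 replicates of 24 subjects with PZ noise
  inflation 3×, and 20 null replicates with homogeneous noise. These sizes
  were fixed by an a-priori power calculation: for two-repeat %CVs the
  per-subject paired effect size under inflation $k$ is
  $d = 1.323(k-1)/\sqrt{k^2+1}$ (half-normal algebra), so $k=3$ with 24
  subjects gives per-replicate power ≈ 0.97 and the ≥90%-of-replicates check
  passes with high probability, while the null side passes with probability
  ≈ 0.92 at the nominal 5% level.
* Default problem sizes used by the tests and the acceptance script — the
  56×56×8 phantom grid, cohorts of 16 (10 patients + 6 volunteers) for the
  qMRI analysis, 3 patients with a central-slab extraction mask for the
  feature-ranking demonstration — were chosen as the smallest configurations
  that keep every region statistically populated after erosion and
  1 mm resampling.

## Known limitations

* The hypoxia-score default is a placeholder contrast, swappable via the
  `combine` argument; conclusions about HS repeatability depend on it.
* Voxel-mode repeatability inherits the %CV's instability near zero-valued
  regions (see above).
* The paired t test assumes approximately normal paired differences of
  %CV values; with very small cohorts the degenerate/untestable guards
  matter more than asymptotics.
* Feature values at gland-edge voxels come from cropped windows and are
  noisier than interior ones; they are included (matching the voxel-wise
  extraction convention) rather than masked away.
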