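Package: qmrirep
Title: Test-Retest Repeatability of Quantitative MRI Parameter Maps and
    Voxel-Wise Texture Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the test-retest repeatability of quantitative
    MRI (qMRI) parameters and voxel-wise radiomic texture features in the
    prostate. Fits parametric maps (two-point ADC, simplified intravoxel
    incoherent motion D and f, a pluggable hypoxia score, mono-exponential R2*,
    and B1-corrected variable-flip-angle T1) from multi-b-value diffusion,
    multi-echo gradient-echo and spoiled-gradient-echo series; extracts
    sliding-window texture-feature maps (GLCM, GLRLM, GLDM, NGTDM) from T2w
    images and parameter maps; and computes QIBA-style repeatability statistics
    (percent coefficient of variation, within-subject %wCV, and the
    repeatability coefficient %RC = 2.77 x %wCV) in both region-of-interest and
    voxel-wise modes, with zone and tissue dependency testing and feature
    ranking. Includes a synthetic test-retest prostate phantom (forward signal
    models with Rician noise, zone-dependent noise, inter-session jitter and
    drift) so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
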