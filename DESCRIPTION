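Package: natriq
Title: Quantitative Sodium MRI of Calf Muscle: Simulation, Correction, and Repeatability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantitative sodium (23Na) MRI of human calf muscle at
    ultra-high field: density-adapted 3D radial (DA-3DPR) trajectory
    construction and point-spread-function simulation, Kaiser-Bessel gridding
    reconstruction, coil combination and B0/B1+ field mapping with intensity
    and off-resonance corrections, ROI-based T1 and bi-exponential T2*
    relaxometry, geometric-transfer-matrix partial-volume correction,
    calibration-phantom-based tissue sodium concentration (TSC) computation,
    and repeatability statistics (two-way ICC, Bland-Altman agreement, exact
    Friedman and Wilcoxon tests). A synthetic digital calf phantom generator
    makes the full pipeline testable end to end without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
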