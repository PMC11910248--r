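Package: bstarsim
Title: Simulation, Reconstruction and MTR Analysis for Half-Radial
    Dual-Echo Balanced SSFP (bSTAR) Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for ultra-high-resolution balanced
    steady-state free precession (bSSFP) brain MRI at low field using the
    half-radial dual-echo bSTAR acquisition. Provides closed-form bSSFP and
    SPGR steady-state signal models with banding/passband analysis and
    flip-angle matching between phantom and tissue; 3D (and 2D-analog)
    center-out/center-in radial trajectory design on an Archimedean spiral
    with gradient-impulse-response (GIRF) correction and radial density
    compensation; seeded digital phantoms (resolution-rod and brain-like,
    with MTR ground truth, smooth off-resonance fields and synthetic coil
    maps); a k-space forward simulator; gridding (adjoint) and
    wavelet-regularized FISTA compressed-sensing reconstruction with coil
    sensitivity estimation and per-echo complex combination; and
    magnetization transfer ratio (MTR) mapping with dual-echo B0 field
    maps, histogram-peak repeatability statistics and ROI apparent SNR.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
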