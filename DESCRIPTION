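Package: mlnrecon
Title: Minimal Linear Networks for MR Image Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Complex-valued minimal linear networks for magnetic resonance
    image reconstruction. Provides axis-dependent subspace-connected linear
    layers (fully connected, shared or independent weights per tensor axis),
    MR-physics forward simulators for multi-coil Cartesian and non-Cartesian
    spiral acquisitions with time-segmented B0 inhomogeneity correction, a
    synthetic training corpus (multi-ellipse phantoms and procedural
    brain-like images with random smooth phase), trainable k-space plus
    image-domain (k+I) reconstruction networks fitted by Adam with L1 loss,
    parameter accounting for the network topologies, and evaluation tools
    (SSIM, NRMSE, pseudo-replica noise maps, kernel RMS and segment maps).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
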