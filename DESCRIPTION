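Package: octinvasion
Title: Quantification of Cancer Cell Invasion in 3D Organotypic Models
    from Optical Coherence Tomography Volumes
Version: 0.1.0
Author: Kenta Morishita [aut, cre]
Maintainer: Kenta Morishita <kenta.morishita@example.org>
Description: Tools for quantitative, longitudinal monitoring of cancer cell
    invasion in scaffold-based 3D organotypic cancer models imaged by optical
    coherence tomography (OCT). Provides a synthetic OCT phantom generator
    with programmed ground truth (speckle, depth attenuation, anisotropic
    point-spread blur), lossless multi-page TIFF volume I/O, a trainable
    voxel classifier for semantic segmentation of cancer versus stroma, a
    partition of the cancer mask into the original cancer cell region and the
    invasive cancer cell region (ICCR), 3D invasion metrics (ICCR volume,
    hypothetical-invasion-front surface area, mass invasion index, depth of
    invasion), 2D histomorphometric section metrics, and the two-factor
    statistical comparison design (Welch's t-test, exact Mann-Whitney U).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
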