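Package: ApicalQuant
Title: Quantitative Image Analysis of Apical Surface Flattening and
    Endosome Dynamics in Cellularizing Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipelines for quantifying apical plasma-membrane remodelling
    from fluorescence time-lapse microscopy of the early Drosophila embryo:
    fractional protrusion coverage via an oriented Mexican-hat (Ricker x
    Gaussian) filter bank with skeleton-based readout, puncta counting with
    robust-background thresholding and early-baseline normalization,
    sub-apical structure counts in calibrated regions, gated optimal-assignment
    particle tracking with apical-persistent versus basally-descending
    classification against the cellularization furrow, and object-based
    two-channel colocalization. Includes seeded synthetic-movie generators
    that provide ground truth for every stage, an exact small-sample
    two-sample Kolmogorov-Smirnov test, and calibrated TIFF/CSV input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    EBImage,
    tiff,
    igraph,
    yaml,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: ImageAnalysis, CellBiology, Software
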