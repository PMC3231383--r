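Package: canopyfuse
Title: Fused Mobile Laser Scanning and Hyperspectral Data for Tree Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying individual trees from fused mobile laser
    scanning (MLS) point clouds and hyperspectral line-scanner data. Provides
    a synthetic garden-scene generator (conifer and broadleaf crown models,
    species reflectance curves, line-spectrometer frame simulation with
    Spectralon-style reference normalization), point/pixel fusion, extraction
    of 34 canopy height-distribution features and 123 per-tree mean
    reflectance features, and a classification protocol built around an
    RBF-kernel support vector machine evaluated by leave-one-out
    cross-validation: exhaustive single and pair feature searches,
    top-fraction pair selection, mixed structural/spectral feature
    quadruples, greedy forward selection, and a linear discriminant baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
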