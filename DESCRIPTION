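Package: dispersim
Title: Simulation and Quantification of Ischemic Tumor Spheroid Dispersal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how ischemia (combined oxygen/nutrient
    deprivation and acidification) drives tumor cell dispersal in
    gradient culture chambers. Provides a two-cell-type cellular Potts
    simulator of core/cortical spheroids in extracellular matrix;
    morphometry of spheroid invasiveness (perimeter over equal-area
    circle perimeter), ratiometric fluorescence and pH estimation,
    Delaunay-based local cell density, and matrix-degradation scoring;
    single-cell migration statistics (speed, persistence, runner
    classification, mean-squared-displacement power-law fitting with
    bootstrap confidence intervals, and circular directional tests);
    drug-gradient estimation from intensity profiles; and seeded
    synthetic-data generators for every input class so the full
    pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
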