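Package: volkrig
Title: Forest Stand Volume Estimation from Multi-Source Remote Sensing with
    Residual Kriging Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates plantation stand volume (m3/ha) from field plots,
    airborne LiDAR point clouds, and visible-band (RGB) imagery. Provides
    species-specific binary volume equations, extraction of visible vegetation
    indices, gray-level co-occurrence texture features and terrain factors,
    LiDAR canopy height/density/intensity metrics with simple tree detection,
    Pearson correlation screening, random forest / support vector / neural
    network regressors with a uniform contract, and from-scratch residual
    geostatistics (empirical semivariograms, spherical and Gaussian model
    fitting, ordinary kriging) to build regression-kriging hybrid estimators.
    Includes a seeded synthetic landscape generator with known ground truth so
    every stage is testable by parameter recovery, plus leave-one-out
    cross-validation of all base and hybrid models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    jsonlite,
    ranger,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
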