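Package: spacekit
Title: Spatial Control and Space-Generation Metrics for Soccer Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies spatial control in soccer from player and ball tracking
    data. Builds data-driven per-player movement models from trajectory
    triplets via kernel density estimation, normalizes them into player
    influence surfaces, and combines team influences into pitch control. A
    feed-forward network learns defensive influence as a function of ball
    position, yielding a pitch-value surface; their product defines space
    quality, from which per-player space-generation metrics for passers and
    receivers are derived. Includes the classical bivariate-Gaussian player
    influence model as a baseline, a pass distance-to-duration regression, and
    a kinematically constrained synthetic match simulator with plantable
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    e1071,
    pROC,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
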