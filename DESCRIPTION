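Package: relaxransac
Title: Preprocessed RANSAC for Two-View Correspondence Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Robust two-view geometric verification of putative feature
    correspondences. A relaxation-labeling prefilter scores every putative
    match by the geometric consistency of its neighbours and extracts a
    reduced, high-confidence subset on which a fundamental matrix (normalized
    eight-point) or homography (normalized DLT) is estimated by adaptive
    RANSAC with bucketed minimal-subset sampling; inliers are then classified
    on the full putative set. Includes a Harris-corner plus normalized
    cross-correlation front-end, a ground-truth synthetic two-view scene
    generator for benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
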