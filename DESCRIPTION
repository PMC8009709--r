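Package: scanmetry
Title: Accuracy Assessment of Dental Scan Systems on a Synthetic Integration Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking dental surface scanners (intraoral and
    extraoral) against a machined single-tooth "integration model". Generates
    the parametric reference model as a watertight triangle mesh from its six
    design indices (two radii, three heights, one occlusal inclination angle),
    simulates replicate scans with controlled surface noise, low-frequency
    stitching drift, pose perturbation and decimation, recovers the six
    indices from any scan by least-squares primitive fitting (plane, cylinder,
    cone), registers scans to the gold standard by iterative closest point and
    computes signed surface deviations and RMS, and summarises a study as
    ISO 5725-style trueness and precision (scaled x1000) with replicate RMS,
    95% confidence intervals and Kruskal-Wallis group comparisons. Meshes are
    read and written as binary or ASCII STL.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
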