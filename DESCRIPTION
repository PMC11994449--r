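Package: hetbench
Title: Benchmarking Toolkit for Single-Sample Tumor Subclonal Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an evaluation framework for single-sample tumor
    subclonal reconstruction: truth phylogeny modeling, the seven subchallenge
    scoring metrics (purity, subclone number, cellular-prevalence profiles via
    earth mover's distance, mutation coclustering via precision-recall and
    Jensen-Shannon divergence, and phylogeny relation-matrix correlation),
    random and one-cluster baseline predictors, score normalization with
    bootstrap rank significance and multicriteria decision analysis, consensus
    ensemble methods (median, floor-of-median, WeMe, CICC), tumor-intrinsic
    feature computation (NRPCC, PGA, clonal fraction, peak overlap), and a
    synthetic cohort generator with noise-degraded predictions so the whole
    framework is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
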