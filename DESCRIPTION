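Package: meltplex
Title: Multiplex Digital PCR Melting-Curve Genotyping and Poisson Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Toolkit for multiplex digital PCR combined with melting-curve
    analysis. Simulates partitioned-chip fluorescence data for a 14-target
    KRAS/GNAS/RPP30 assay (Poisson loading, fragment-length-dependent
    detectability, logistic melt transitions, additive noise, PCR-error false
    positives), calls per-well melt peaks (Tm, FWHM) by smoothed negative
    differentiation, classifies well genotypes including shared-dye
    double-positive wells, and quantifies variant allele frequencies and
    copy-number-alteration ratios with Poisson statistics, Wilson confidence
    intervals, limit-of-detection and linearity evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
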