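Package: footprintMS
Title: Exometabolome Footprinting Analysis for Flow-Injection MS/MS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for targeted and semi-targeted metabolic
    footprinting by dilute-and-shoot flow-injection tandem mass spectrometry.
    Provides isotope-dilution (IDMS) calibration and quantification,
    signal-to-noise filtering, pooled-QC anchored signal-drift correction
    (LOESS smoothing with leave-one-out span selection and a cubic-spline
    correction function), QC-based feature thresholding, MAR/MNAR-aware
    imputation, range scaling, PCA and multi-class PLS-DA with stratified
    double cross-validation, bootstrap confidence intervals for regression
    coefficients and class-specific VIP scores, variable selection,
    Kruskal-Wallis/post-hoc univariate statistics with Benjamini-Hochberg
    correction, hierarchical clustering with correlation distance, pathway
    over-representation and betweenness-centrality topology analysis, and
    bioprocess key performance indicators. A synthetic-data module emulates
    the measurement structure (interleaved QC injections, injection-order
    drift, lognormal noise, MAR and left-censored missingness) so that every
    stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    igraph,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
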