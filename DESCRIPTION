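Package: physage
Title: Physiological Age and Lifespan-Biomarker Signatures from Aging
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying inter-individual heterogeneity in aging with
    bulk RNA-seq. Builds an average aging transcriptome trajectory from a
    time course of pooled samples, estimates each sample's physiological
    (transcriptional) age by projection onto a principal curve fitted through
    the time series in principal-component space, and decomposes the gene
    expression signature of lifespan-predictive biomarkers into an
    age-aligned component and an age-orthogonal component. Includes
    negative-binomial GLM differential expression with a polynomial age
    design, dynamic-time-warping trajectory clustering with barycenter
    averaging, gene set enrichment and hypergeometric over-representation,
    Kaplan-Meier/log-rank survival comparison of biomarker-sorted
    subpopulations, and a synthetic aging-cohort generator with full ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
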