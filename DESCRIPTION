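Package: corrzidf
Title: Distribution-Free GEE for Correlated Zero-Inflated Longitudinal Count Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-part (zero / non-zero) functional response modelling of
    longitudinal zero-inflated count data, as arises in time-course
    metagenomic and microbiome studies. Each feature is modelled through a
    zero indicator and the raw count, with logit and log link mean functions
    and zero-inflated Poisson working variances, estimated by generalized
    estimating equations under independence, AR(1) or exchangeable working
    correlation assembled from 2x2 time-point blocks. Robust sandwich
    covariances yield per-feature Wald tests on the count-part coefficients,
    with Benjamini-Hochberg false discovery rate control across features.
    Includes a Gaussian-copula simulator of two-group longitudinal
    zero-inflated count studies for power and type-I-error evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, TimeCourse, DifferentialAbundance,
    Regression, Software
RoxygenNote: 7.3.3
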