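Package: metabopred
Title: Predictive Metabolomics from Microbial Community Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Trains per-metabolite elastic net regression models that link
    microbial sequence-feature relative abundances (taxa, OTUs, or gene
    families) to community metabolite relative abundances, and applies the
    trained weight matrix to predict composite metabolomes for new
    communities.  Includes the compositional preprocessing the models
    require (total-sum scaling, prevalence/abundance and variance filters,
    rank-based inverse normal transformation of predictors, arcsine square
    root transformation of responses with exact back-transformation),
    cross-validated hyperparameter selection scored by Spearman
    correlation, a representativeness score (RTSI) for new samples based on
    Tracy-Widom selection of significant principal components of the
    training feature space, permutation-based null significance testing
    with within-sample renormalization, and feature-set enrichment analysis
    (permutation Kolmogorov-Smirnov enrichment scores and one-tailed Fisher
    over-representation with Benjamini-Hochberg FDR control).  A synthetic
    data generator with known sparse ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
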