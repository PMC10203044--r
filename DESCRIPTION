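Package: refpgs
Title: Polygenic Scores for Refractive Error: Derivation, Evaluation and
    Myopic Maculopathy Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates genotype-phenotype cohorts with block linkage
    disequilibrium and an age-of-onset-of-spectacle-wear (AOSW) observation
    process, and implements a complete polygenic score (PGS) pipeline for
    refractive error: covariate-adjusted single-variant association
    testing, leave-one-chromosome-out inference of refractive error from
    AOSW, multi-trait meta-analysis of summary statistics with a two-stage
    union assembly, LD-aware point-normal Gibbs shrinkage with grid tuning
    plus a clumping-and-thresholding baseline, evaluation of scores by
    incremental R-squared, AUROC, tail odds ratios and decile risk with
    bootstrap confidence intervals, and a family-aware cross-fitted test of
    whether the PGS predicts severe myopic macular degeneration beyond
    refractive error, using nested standard and Firth-penalised logistic
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
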