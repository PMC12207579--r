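Package: tetrablup
Title: Tetrasomic Diallel Analysis with Pedigree and Single-Step Genomic BLUP
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative-genetic analysis of autotetraploid (e.g. potato)
    incomplete diallel populations. Builds tetrasomic pedigree relationship
    matrices with a double-reduction parameter, tetraploid VanRaden genomic
    relationship matrices from 0-4 allele dosages, and blended single-step
    H matrices; estimates additive, family (specific combining ability),
    line and residual variance components by average-information REML;
    predicts breeding values with prediction error variances; quantifies
    prediction accuracy by repeated random k-fold cross-validation; and
    estimates phenotypic and additive genetic correlations from pairwise
    bivariate models. A tetrasomic diallel simulator with gene dropping,
    cytoplasmic male sterility and maternal cytoplasm transmission makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
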