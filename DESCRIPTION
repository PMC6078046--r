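Package: carpyield
Title: Genetic Parameters and Selection Response for Slaughter Yields in Common Carp
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative-genetic analysis of slaughter yields
    (headless carcass and filet) and their in vivo morphological predictors in
    common carp. Implements construction of log-log allometric residual yield
    traits with quality-control filtering, landmark-based geometric
    morphometrics (interlandmark distances, polygon areas, generalized
    Procrustes analysis and shape-on-covariate regression), best-subset
    multiple regression with K-fold cross-validation for yield prediction,
    restricted maximum likelihood estimation of variance components under the
    pedigree animal model (heritabilities, genetic and phenotypic correlations
    with standard errors and likelihood-ratio tests), prediction of genetic
    gain under mass, full-sib and indirect truncation selection, and a
    synthetic-study generator that emulates a partial factorial mating design
    with a configurable multivariate trait architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
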