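Package: twinpath
Title: Multivariate Cholesky Twin Models and DeFries-Fulker Extremes Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the classical twin design: simulation of twin-pair
    cohorts with known additive genetic (A), shared (C) / non-additive (D),
    and nonshared (E) variance structure; data preparation (log
    transformation, residualization on sex and age, z-scoring); cross-twin
    and cross-trait cross-twin correlations by zygosity-sex group;
    full-information maximum-likelihood fitting of saturated and Cholesky
    ACE/ADE/AE/CE/E models with quantitative sex limitation, correlated
    factors standardization, genetic correlations, bivariate heritability,
    likelihood-ratio model comparison and profile-likelihood confidence
    intervals; and DeFries-Fulker extremes regression with proband
    selection, group heritability, bivariate cross-trait estimates and the
    extremes genetic correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
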