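Package: diffuseGC
Title: Molecular Subtyping and Treatment-Responder Estimation for Diffuse-Type Gastric Cancer Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational analysis of diffuse-type gastric
    cancer expression and mutation cohorts: cross-cohort normalization
    (counts-per-million, quantile normalization, log2 transform, iterative
    median centering, per-dataset z-standardization and pooling), two-group
    differential expression with pooled-variance t-tests and fold-difference
    filters, hierarchical clustering with centered-correlation similarity and
    centroid linkage, a Bayesian compound covariate predictor for the four
    TCGA gastric cancer subtypes (EBV, MSI, GS, CIN) composed into a
    one-vs-rest decision tree with leakage-free cross-validation,
    mutation-frequency and tumor-mutational-burden statistics with Pearson
    chi-square contingency tests and MSI-H calling, and estimation of the
    expected fraction of responders to immune checkpoint and mTOR inhibitors.
    Includes a negative-binomial multi-cohort simulator with planted subtype
    signatures, batch effects and subtype-dependent mutation burden, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    limma,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
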