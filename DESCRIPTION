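Package: ggnquant
Title: Quantitative CT Analysis of Ground-Glass Lung Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for first-order quantitative CT analysis of pulmonary
    ground-glass nodules (GGNs). Provides a synthetic 3D nodule phantom
    generator emulating a three-class adenocarcinoma cohort (in situ,
    minimally invasive, invasive), NIfTI volume and mask input/output with
    segmentation and cohort-inclusion contracts, a feature engine computing
    histogram percentiles, texture entropy and uniformity, nodule size,
    volume, density and mass, and a statistics stage chaining one-way ANOVA
    with Bonferroni post hoc tests, Spearman correlation against invasion
    extent, two-observer intraclass correlation, variance-inflation-factor
    screening, backward-stepwise logistic regression, ROC analysis and a
    two-threshold invasiveness classification rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
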