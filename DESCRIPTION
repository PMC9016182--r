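Package: hdmethmediate
Title: High-Dimensional DNA Methylation Mediation Analysis for Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Epigenome-wide causal mediation analysis linking a binary exposure
    to a binary outcome through high-dimensional DNA-methylation mediators.
    Implements array-style quality control and normalization of beta-value
    matrices, reference-based cell-type deconvolution, baseline association
    statistics, sure independence screening of candidate mediator CpG sites,
    de-sparsified (debiased) LASSO inference for the logistic outcome model
    with false-discovery-rate selection, counterfactual estimation of average
    causal mediation effects (ACME) and average direct effects (ADE) with
    nonparametric bootstrap intervals, and a correlated-errors sensitivity
    analysis in the sensitivity parameter rho. Includes a synthetic-cohort
    generator with known mediation truth so the full pipeline is testable
    without access to raw array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    limma,
    pracma,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
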