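Package: btnet
Title: Boolean Threshold Network Inference from Binarized Expression Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers executable gene regulatory networks from time-series or
    pseudo-time-ordered single-cell expression data by fitting per-gene
    penalized logistic regressions to binarized expression states and
    converting the coefficients into Boolean threshold update rules. The
    result is a signed, weighted, directed network together with a dynamical
    model that can be simulated synchronously. Includes perturbation-based
    design conditioning for collinear binary data, significance-based edge
    calling, structural (AUROC, AUPR, accuracy) and dynamical evaluation
    against gold-standard networks, and a fully synthetic benchmark built
    around a nine-gene threshold network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
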