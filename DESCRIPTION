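Package: vdlin
Title: Signature-Based Virtual Screening of Dual-Action Immunomodulatory Compounds
Version: 0.1.0
Authors@R: person("VDLIN", "Maintainers", email = "maintainers@vdlin.dev", role = c("aut", "cre"))
Description: A compound-screening toolkit that predicts the effect of a small
    molecule on a ten-gene innate-immunity panel directly from its chemical
    structure (SMILES), and ranks candidates that simultaneously suppress five
    NF-kB-driven inflammatory genes (IL1B, IL6, TNF, PTGS2, NOS2) and activate
    five IFN-I/EGR1 genes (EGR1, IFNB1, ISG15, IFIT3, CXCL10). Structures are
    parsed under a minimal SMILES grammar into production-rule one-hot arrays,
    compressed by a variational autoencoder, and fed to a multi-task 1D
    convolutional network trained with a joint loss that couples expression
    regression to a differentiable surrogate of an indicator-based
    immunomodulatory score. Includes a seeded synthetic-library generator with
    a planted structure-activity rule, a two-stage screening pipeline, a
    Gaussian-process Bayesian hyperparameter tuner, five conventional
    machine-learning baselines, and a label-noise robustness benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
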