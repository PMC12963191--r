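Package: tissueload
Title: Layered Soft-Tissue Indentation Mechanics and Exposure Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Axisymmetric nonlinear finite element analysis of layered
    skin-adipose-muscle tissue under localized circular pressure loads,
    with Neo-Hookean hyperelasticity, mean-dilatation treatment of
    near-incompressibility, and adaptive load incrementation. Includes
    post-processing to von Mises stress and effective (logarithmic)
    strain fields, volume-weighted percentile reference thresholds,
    exceedance curves, AUC-based and volume-fraction tissue-exposure
    metrics, built-in anatomical model parameterizations, analytic
    solver benchmarks, and synthetic field generators for pipeline
    validation. Intended for comparative deep-tissue-injury risk
    modelling across anatomical variants, pressures, and tissue
    softening scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
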