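Package: protage
Title: Proteomic Age Clocks and Case-Cohort Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct, train and apply linear proteomic age clocks (including
    organ-specific clocks and a Global ensemble), derive lowess-detrended age-gap
    z-scores, and relate them to mortality and incident disease risk with
    Prentice-weighted stratified Cox models under a case-cohort design. Includes
    a synthetic cohort generator with latent aging acceleration and
    Gompertz-Makeham survival, multivariate QC outlier detection, cross-sectional
    risk-factor models with a healthy lifestyle index, Gompertz-Makeham
    age-relatedness fitting, lasso-based clock selection, Harrell concordance
    comparison, and a configuration-driven analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    survival,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
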