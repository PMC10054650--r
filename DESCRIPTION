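Package: quantalmix
Title: Quantal Dose-Response Analysis and Toxin Mixture Synergism for
    Larvicide Bioassays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maximum-likelihood logit and probit analysis of quantal
    (dead/alive) larvicide bioassays on the log10 concentration scale:
    LC50 and general LCp estimation with Fieller (fiducial) or delta-method
    confidence limits, Pearson goodness of fit with Finney's heterogeneity
    correction, Abbott's control-mortality correction, and activity
    screening with censored ("greater-than") LC50 reporting. For binary
    toxin mixtures it computes the expected LC50 under the simple-similar-
    action no-interaction model, synergism and enabling factors, and an
    interaction classification that handles individually non-toxic
    (censored) components. A synthetic bioassay generator reproduces
    serial-dilution designs with binomial mortality so the whole pipeline
    can be exercised and calibrated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
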