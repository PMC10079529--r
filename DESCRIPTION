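Package: planknet
Title: Time-Varying Causal Network Inference for Plankton Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs time-varying causal interaction networks from
    monthly multivariate ecological time series using convergent
    cross-mapping (CCM) with seasonal-surrogate correction, computes
    network properties (connectance, interaction strength, trophic
    control, interaction-type structure), and models those properties
    over temperature and phosphate gradients with multivariate S-maps.
    Includes a seasonally forced multispecies Ricker simulator with
    known directed topology so every stage of the pipeline can be
    validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    zoo,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
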