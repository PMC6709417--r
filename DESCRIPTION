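Package: ebfdtm
Title: Streamlined Deuterium Dose-to-Mother Designs for Classifying
    Exclusive Breastfeeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the deuterium oxide dose-to-mother (DTM) technique
    used to classify mother-infant pairs as exclusively breastfeeding (EBF)
    or not. Implements the linked one-compartment water-kinetics model for
    maternal and infant saliva enrichment, Bayesian estimation of the four
    individual kinetic parameters by adaptive Markov chain Monte Carlo under
    low-information, informative, or mixed priors, a posterior-probability
    classifier based on the infant's non-milk water intake rate, and a
    pseudo-exhaustive search over streamlined (reduced) sampling schedules
    scored by sensitivity and specificity against the full-design reference
    classification. A synthetic-cohort generator reproduces the statistical
    structure of multi-country DTM field studies so the whole pipeline can
    be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
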