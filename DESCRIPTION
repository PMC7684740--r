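Package: smokemnar
Title: Missing-Not-at-Random Sensitivity Analysis for Registry Smoking Prevalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate whether voluntarily reported maternal smoking in a
    birth registry is biased by non-consent missingness. Implements a
    small-for-gestational-age (SGA-10) based calibration of a
    missing-not-at-random (MNAR) target smoking prevalence, log-risk regression
    of unknown-status risk with mother-clustered robust variance,
    prevalence-matched classifiers that predict smoking among mothers with
    unknown status, and combination of observed and predicted prevalence into
    annual series. A synthetic birth-registry generator with configurable
    MAR/MNAR missingness stands in for access-restricted registry microdata so
    the whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    sandwich,
    jsonlite,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
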