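Package: ednadetect
Title: Bayesian Analysis of Environmental DNA Detection Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing detection/non-detection records of
    environmental DNA (eDNA) water samples from stratified pond or
    mesocosm experiments. Fits Bayesian hierarchical logistic regression
    models of per-sample detection probability by adaptive random-walk
    Metropolis MCMC, with optional section- and transect-level random
    intercepts; ranks candidate models by the deviance information
    criterion (DIC) and DIC weights; assesses fit with posterior
    predictive Bayesian p-values; estimates per-sample false-positive
    rates from zero-detection control data; and converts fitted models
    into survey-design quantities (cumulative detection probability and
    the number of 1-L samples required for a target certainty). Includes
    a stratified-design simulator and the bundled African jewelfish pond
    experiment data for worked examples and parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), rjags, yaml, jsonlite, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
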