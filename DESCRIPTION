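Package: gsmring
Title: Gaussian Scale Mixture Observers and Stochastic E-I Ring Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying perceptual inference with a Gaussian scale
    mixture (GSM) ideal observer and with stochastic stabilized supralinear
    ring networks of excitatory and inhibitory neurons that sample from GSM
    posteriors. Implements the GSM generative model with an oriented Gabor
    feature bank, exact conditional and contrast-marginalized posteriors, a
    hypoprior perturbation that broadens the prior, synthetic stimulus banks,
    an Euler-Maruyama simulator for rate networks with Ornstein-Uhlenbeck
    process noise, moment-matching calibration of ring kernels to observer
    posteriors, an inhibitory-deficit perturbation with homeostatic
    excitatory scaling, and analyses of stationary response moments, LFP
    power spectra with gamma-band statistics, onset transients, and recurrent
    E/I input decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
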