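Package: thermotk
Title: Temperature-Dependent Toxicokinetic Modelling for Aquatic Invertebrates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits one-compartment and first-order biotransformation-cascade
    toxicokinetic models to bioconcentration time series of aquatic
    invertebrates, with replicate weighting, profile-likelihood confidence
    intervals and AIC-based model selection. Derives kinetic and apparent
    bioconcentration factors, analyses the temperature dependence of uptake,
    elimination and biotransformation rates through Arrhenius regression,
    tests bioconcentration factors for temperature trends, and simulates
    internal concentrations under time-varying temperature and exposure
    using Arrhenius-scaled rates and Heun's predictor-corrector method.
    Includes a synthetic-experiment generator emulating standard
    uptake-elimination study designs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
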