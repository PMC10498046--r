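Package: tissuegrowth
Title: Stochastic Birth-Death and Refractory-Period Models of Tissue Growth
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulators and exact analytics for two minimal stochastic models
    of tissue size: a continuous-time Markovian birth-death branching process
    with proliferation rate sigma and apoptosis rate kappa, and a
    non-Markovian pure-birth model in which each cell must wait through a
    refractory period T after division before it can divide again (rate
    gamma0 thereafter). Provides closed-form moments, extinction
    probabilities and two-time correlation functions for the Markovian model,
    the Lambert-W pole spectrum, pole-expansion mean, effective Malthusian
    growth rate and oscillation period for the refractory model, a
    renewal-equation solver for non-Markovian moments, discrete-time and
    exact event-driven ensemble simulators, ensemble estimators (moments,
    connected and Pearson two-time correlations with jackknife errors,
    extinction fraction, exponential/power-law fits, oscillation-period
    detection), and a command-line interface with figure-level reproduction
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
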