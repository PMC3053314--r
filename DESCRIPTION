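Package: channoise
Title: Channel Noise in Conductance-Based Model Neurons by Diffusion
    Approximation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating stochastic ion-channel gating ("channel
    noise") in single-compartment conductance-based neuron models. Any Markov
    kinetic scheme with gating-variable-dependent rates is translated into an
    effective stochastic conductance in which deterministic gating variables
    are complemented by a sum of Ornstein-Uhlenbeck processes matching,
    analytically, the stationary mean and multi-exponential autocovariance of
    the fraction of open channels. The package also provides the exact
    microscopic Monte-Carlo simulator of channel-state occupancy counts, the
    classical Fox-Lu Langevin approximation as a comparator backend, a
    current-balance membrane integrator with interchangeable channel-noise
    backends, voltage- and current-clamp protocols, and the spike-train and
    spectral statistics (ISI CV, firing efficacy and latency, spike-timing
    reliability and precision, Welch power spectral density) used to compare
    them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix
Config/testthat/edition: 3
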