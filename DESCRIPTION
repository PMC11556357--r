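Package: binocgain
Title: Two-Stage Binocular Contrast Gain Control Modelling and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the two-stage model of binocular contrast gain
    control (interocular suppression followed by binocular summation and a
    second nonlinearity) and its extension to three parallel post-retinal
    pathways (achromatic, L-M, S-(L+M)) with a full matrix of interocular
    cross-pathway suppression. Provides threshold solving and dipper-function
    generation for the four classic ocular arrangements (monocular,
    binocular, half-binocular, dichoptic), a stochastic two-interval
    forced-choice observer with 3-down-1-up staircase and
    method-of-constant-stimuli engines, Bayesian psychometric-function
    estimation (cumulative Gaussian on dB contrast), multi-start simplex
    least-squares fitting of threshold data, and hierarchical Bayesian
    fitting of trial-level binomial data via MCMC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
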