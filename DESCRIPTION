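Package: qsnoise
Title: Stochastic Noise in Quorum-Sensing Signalling Near the Activation
    Threshold
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact multicellular Gillespie simulation and closed-form
    stationary analytics for a telegraph-mRNA-driven model of
    autoinducer production in quorum-sensing bacterial populations below
    the activation threshold. Cells exchange the signalling molecule with
    a shared, well-stirred extracellular pool by passive diffusion.
    Provides the stationary density, mean, support and shape
    classification of the reduced dichotomous-noise model, the
    transcriptional (mRNA-switching) noise in closed form, a
    piecewise-deterministic Markov process simulator of the reduced
    equation, a dual-reporter variant of the full stochastic model, and
    intrinsic/transcriptional noise decomposition including the
    diffusion-scan experiment that exhibits the non-monotonic dependence
    of total noise on the diffusion rate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
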