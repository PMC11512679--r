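Package: popcomm
Title: Population Communication and Receptive-Field Models of Auditory Encoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and fitting toolkit for studying how nonlinear sound
    encoding arises along the ascending auditory pathway. Generates dynamic
    random chord (DRC) stimuli as dB-SPL cochleagrams, simulates hierarchical
    spiking populations (midbrain, thalamus, cortex) with Poisson variability
    and optional between-neuron spike coupling, and fits linear-nonlinear
    encoding models: spectrotemporal receptive fields (STRF), population
    communication models (PCM), network receptive fields (NRF), and two-stage
    models. Model performance is evaluated with the normalized correlation
    coefficient (CC_norm) on held-out stimulus segments, and single-trial
    spike-train coupling is characterized with a penalized Poisson GLM using
    raised-cosine temporal bases. Includes nonparametric model-comparison
    statistics with bootstrap confidence intervals and reproducible
    experiment orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    glmnet,
    nnet,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
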