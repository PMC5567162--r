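Package: jrnmm
Title: Stochastic Jansen-Rit Neural Mass Model with Splitting Integrators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of the stochastic Jansen-Rit neural mass
    model formulated as a damped stochastic Hamiltonian system with additive
    noise. Provides exact-sub-flow splitting integrators (Ornstein-Uhlenbeck,
    Wiener and Strang variants) alongside an Euler-Maruyama baseline,
    closed-form transition covariances, analytic first- and second-moment
    envelopes and Gaussian pathwise escape bounds, noise calibration,
    mean-square convergence-order estimation, long-run invariant-measure
    density estimation of the EEG-like output signal, and a command-line
    interface with scenario presets for alpha-rhythm regimes.
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
    ggplot2,
    generics,
    jsonlite,
    deSolve,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Matrix
Config/testthat/edition: 3
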