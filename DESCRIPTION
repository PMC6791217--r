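Package: oncodelay
Title: Multi-Delay Dynamics of Oncolytic Virotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and stability analysis of a three-compartment model of
    oncolytic virotherapy (uninfected tumor cells, infected tumor cells, free
    virus) in which viral transmission is split over multiple discrete delays
    representing the stages of the lytic cycle. Provides the basic reproduction
    number and closed-form equilibria, a delay-differential-equation simulator
    with dense trajectory evaluation, linear stability analysis at the
    therapy-failure and endemic equilibria (spectra, Routh-Hurwitz tests,
    delay-robustness certificates), Hopf bifurcation analysis for the
    single-delay case (crossing frequency, critical delay, transversality),
    Lyapunov-functional diagnostics, preset scenarios, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
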