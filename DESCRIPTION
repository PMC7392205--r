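Package: thquorum
Title: Quorum-Sensing Dynamics of T Helper Cell Effector Choice
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of a four-variable model of CD4+ T helper
    (Th1 versus Th2) effector choice, in which the master transcription factors
    T-bet and GATA3 self-activate and cross-inhibit within cells while the
    master cytokines IFN-gamma and IL-4 accumulate, self-amplify and
    cross-inhibit in the shared extracellular space. Cytokine production and
    removal scale with cell density, so the collective behaviour of a Th group
    bifurcates from stable mixed effector types at culture densities to
    unified polarized commitment above a quorum density. The package provides
    deterministic integration, equilibrium location and linear stability
    analysis, bifurcation scans over secretion strength and cell density, a
    within-scale versus cross-scale stability decomposition, antigen-presenting
    cell (APC) instruction schedules and reversal-window timing, stochastic
    (Euler-Maruyama) ensembles with multiplicative noise, discernment scoring
    of time-varying instruction, and Monte-Carlo parameter sensitivity
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
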