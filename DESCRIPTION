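Package: avshape
Title: Temporal Profiles of Avalanches on Networks via Markov Branching
    Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analyze the temporal profiles of avalanches (cascades) on
    networks with Markov branching-process theory.  Builds offspring
    distributions from network degree distributions combined with
    dynamics-specific vulnerability models (threshold, neuronal, and
    meme-propagation dynamics), solves the extinction-probability
    differential equation, and evaluates average avalanche shapes
    (terminating, non-terminating, discrete- and continuous-time) together
    with their asymptotic peak-location and coefficient-of-variation forms.
    Includes reproducible stochastic simulators for Galton-Watson and
    continuous-time Markov branching avalanches and for cascade dynamics on
    configuration-model networks, plus estimators for average shapes,
    rescaled shape collapse, events-per-time and replica error bars used as
    criticality diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    igraph,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
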