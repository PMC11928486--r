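Package: benthox
Title: Diel Benthic Oxygen Dynamics and the Eco-Evolution of Oxygen Sensing
Version: 0.1.0
Authors@R:
    person("Maren", "Holt", email = "maren.holt@example.org",
           role = c("aut", "cre"))
Description: Models oxygen dynamics at the sunlit sediment-water interface of
    shallow marine shelves over day-night (diel) cycles, and the
    eco-evolutionary consequences of those dynamics for organisms that differ
    in their capacity for cellular oxygen sensing.  Provides a one-dimensional
    reaction-diffusion model of porewater oxygen spanning the diffusive
    boundary layer and the upper sediment, with temperature (Q10) scaling of
    photosynthetic production and heterotrophic respiration, empirical
    seawater oxygen solubility and diffusivity, redox classification of
    interface time series (anoxic / severely hypoxic / hypoxic / oxic),
    diel summary metrics (day and night maxima, transition times, anoxia
    hours), and a Monte-Carlo ensemble engine over environmental parameter
    ranges.  A companion fitness-generating (G) function model couples
    Lotka-Volterra competition to strategy dynamics and simulates the
    competition between species with efficient and poor oxygen sensing under
    sinusoidal-plus-stochastic environmental forcing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
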