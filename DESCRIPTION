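Package: crowdherd
Title: Evolutionary Lattice-Gas Simulation of Crowded Selfish Herds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolution of movement strategies in selfish prey
    herds whose mobility is restrained by crowding. Prey agents live on a
    wrapped-around (torus) occupancy lattice, perceive local occupancy and
    Moore-neighbourhood sizes, and choose one of four cardinal moves through
    an evolvable 11-input/4-output linear network genotype. Moves into
    occupied cells are blocked (or succeed by position swap with a
    configurable squeeze-through probability), the most exposed fraction of
    the population is removed each generation by truncation selection, and
    vacancies are refilled by uniform crossover with Gaussian mutation.
    Provides an optimised compiled engine and a transparent plain-R reference
    engine with bit-identical seeded trajectories, per-generation metrics
    (neighbourhood and mobility scores, conditional leave-probability
    profiles, genotype likelihood embeddings), comparative squeeze-through
    scans, tidy result tables, ggplot2 plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
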