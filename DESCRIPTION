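Package: flywaysim
Title: Potential-Landscape Simulation of Seabird Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mechanistic, physics-inspired simulator of population-level
    bird migration. Monthly gridded resource fields (chlorophyll-a as a food
    proxy) and wind vector fields on a global latitude-longitude lattice are
    combined into an environmental potential landscape: every cell of ocean
    resource contributes an attractive -1/r term, and the local wind tilts
    the landscape so that downwind moves are energetically downhill.
    Simulated birds perform a lattice random walk whose move probabilities
    follow Maxwell-Boltzmann statistics over the eight neighbouring cells,
    with land excluded and a temperature-like parameter controlling
    randomness. The package provides synthetic-environment generators,
    single-bird and colony-ensemble simulation, (a, kT) parameter sweeps,
    occupancy and endpoint density maps, tidy()/glance() accessors and
    ggplot2 visualisation, plus brute-force oracles for validating the
    potential and probability computations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
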