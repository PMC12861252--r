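Package: mushdry
Title: Mechanistic Multiphase Simulation of Hot-Air Mushroom Drying
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates hot-air drying of shiitake mushroom caps with a
    mechanistic multiphase, multiscale model: a two-phase Flory-Huggins
    description of water activity in the vacuole and biopolymer compartments
    of the hyphae, dual-mode Maxwell viscoelastic relaxation of the cell-wall
    matrix coupled into the sorption isotherm, empirical shrinkage and
    porosity evolution, and coupled moisture-energy transport on a shrinking
    one-dimensional finite-volume grid with convective, radiative and
    evaporative boundary exchange. Includes the least-squares calibration
    machinery (sequential single-factor search over the emissivity and the
    transfer correction factors, and a stepped-relative-humidity dynamic
    vapor sorption simulator for the viscoelastic scaling factors), CPMG
    T2-relaxometry inversion with water-population counting, a
    moisture-temperature cell-membrane-integrity classifier, and synthetic
    data generators so the whole pipeline is testable without laboratory
    records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
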