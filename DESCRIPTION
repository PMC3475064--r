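Package: CellulaseSim
Title: Stochastic Lattice Simulation of Enzymatic Cellulose Hydrolysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Event-driven stochastic simulation of crystalline cellulose
    hydrolysis by endo- and exo-cellulases on a two-dimensional glucan-chain
    lattice. Individual enzyme particles adsorb to explicit surface sites,
    break inter-chain hydrogen bonds, hydrolyze glycosidic bonds and desorb,
    with waiting times drawn by the Gillespie direct method and processive
    cellobiohydrolase translocation modelled as a cleave-and-slide cycle.
    Provides S4 classes for the substrate sheet, enzyme species and
    simulation results, observables (conversion, soluble sugar
    concentrations, binding statistics, degree of synergy), configuration
    validation, and presets for endo-only, exo-only, mixture and sweep
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Rcpp, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
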