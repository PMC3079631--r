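Package: aquaflux
Title: Kedem-Katchalsky Modelling of Water and Cryoprotectant Transport in
    Xenopus Oocytes
Version: 0.1.0
Authors@R:
    person("aquaflux", "maintainers", email = "maintainers@aquaflux.invalid",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of swelling and shrinkage
    assays of Xenopus laevis oocytes expressing aquaporins. Implements the
    two-compartment Kedem-Katchalsky model of coupled water and solute
    transport (hydraulic conductivity Lp, solute permeability Ps, reflection
    coefficient sigma), slope-based estimators of osmotic water permeability
    (Pf) and cryoprotectant permeability (Ps), Boyle-van't Hoff handling of
    the osmotically inactive volume, nonlinear per-oocyte fitting of
    (Lp, Ps, sigma) from shrink-swell trajectories under hypertonic sucrose
    or ethylene glycol, conversion of radiolabel scintillation counts to
    intracellular cryoprotectant concentrations, point-mutation and NPA-motif
    bookkeeping for aquaporin constructs, and a seeded synthetic-data
    generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
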