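Package: thrombodpd
Title: Dissipative Particle Dynamics Simulation of Platelet Adhesion on
    Collagen- and VWF-Coated Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A three-dimensional dissipative particle dynamics (DPD)
    simulator of platelet adhesion and aggregation in wall-bounded
    microchannel flow over protein-coated surfaces. Platelet bonds to the
    coated floor and to other platelets are modelled as viscoelastic
    spring-dashpot elements whose formation and rupture follow Bell-type
    force-dependent stochastic kinetics, with a two-stage maturation from
    reversible to irreversible (fibrin-enhanced) adhesion. Includes the
    DPD unit system with physical-unit conversion, channel geometry and
    parameter presets for collagen- and VWF-coated surfaces, a compiled
    integrator with counter-based reproducible noise, and analysis of
    platelet-covered area, aggregate size distributions, near-wall
    platelet velocities, and velocity-profile shear-rate extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
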