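Package: scafflow
Title: Perfusion Scaffold Cell-Culture Simulation and Stochastic Geometry
    Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coupled simulation of cartilage cell culture on fibrous
    scaffolds under perfusion flow. A parametric four-fiber scaffold unit
    is built from indicator-point displacements (the sagitta relation),
    voxelized, and perfused: steady laminar flow with the growing biomass
    treated as a variable-viscosity penalized medium, two-phase glucose
    transport with Michaelis-Menten uptake, lactate production with
    pH-gated viability, and shear-stress-modulated proliferation. A
    stochastic generate-and-test routine screens candidate geometries by
    their culture efficiency. Linear systems are solved by a geometric
    multigrid preconditioned Krylov core implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'geometry.R'
    'kinetics.R'
    'linsolve.R'
    'flow.R'
    'transport.R'
    'culture.R'
    'design_search.R'
    'io.R'
    'scafflow-package.R'
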