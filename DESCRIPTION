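Package: slitflow
Title: Mesoscale Simulation of Polymers under Flow in Slit Nanochannels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid mesoscale simulator coupling a multiparticle collision
    dynamics (MPCD/SRD) solvent to a bead-spring polymer chain confined in a
    slit nanochannel. Supports Poiseuille and implicit-ion electroosmotic
    driving, with the electroosmotic body force derived from the nonlinear
    Poisson-Boltzmann charge distribution between charged plates. Includes
    screened van der Waals wall attractions, stochastic-reflection no-slip
    walls, a cell-level Maxwellian thermostat, a solvent-free chain Monte
    Carlo sampler for equilibrium reference statistics, and the structural
    and transport observables (monomer density, gyration tensor and
    asphericity, persistence length, velocity profiles, Zimm time and
    Weissenberg number) used to study flow-induced lift forces and
    hydrodynamic focusing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), deSolve, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
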