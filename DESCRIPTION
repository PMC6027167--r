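Package: dpdvesicle
Title: Dissipative Particle Dynamics of Chitosan-Coated Lecithin Nanoliposomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mesoscale simulation toolkit for drug-loaded liposomal
    nanoparticles. Provides coarse-grained bead-spring models of lecithin,
    capsaicin and chitosan (including a block-notation grammar for chitosan
    acetylation sequences), a system builder that assembles a preformed
    spherical bilayer vesicle with solutes and explicit solvent at reduced
    number density three, a dissipative particle dynamics engine (soft
    conservative repulsions, pairwise dissipative/random thermostat,
    harmonic bonds, modified velocity-Verlet integration) with a compiled
    cell-list core, and an analysis layer for planar density maps, radial
    density profiles, potentials of mean force between molecular centers of
    mass, vesicle size, and encapsulation efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
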