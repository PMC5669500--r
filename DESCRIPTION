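Package: phagosim
Title: Dynamically Triangulated Membrane Monte Carlo for Phagophore Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the shape remodeling of fused membrane vesicles with a
    dynamically triangulated Monte Carlo (DTMC) model of the Helfrich bending
    energy, with harmonic constraints on area, volume and bilayer area
    difference. Includes a coarse-grained bead-chain model of the S-shaped
    Atg17 dimer scaffold with square-well membrane adhesion, simulated
    annealing shape-branch scans with barrier extraction, umbrella sampling
    with WHAM free-energy reconstruction, Kramers escape-time estimates, and
    a descriptor-based vesicle shape classifier (tube, disk, paddle, bowl,
    cup/phagophore, starfish). Meshes can be exported to PLY, OFF and legacy
    VTK formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
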