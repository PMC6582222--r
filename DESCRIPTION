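Package: smdkin
Title: Steered-Pulling Work, Jarzynski Free Energies, and Eyring Kinetics
    for Stepwise Reaction Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolchain for the free-energy and kinetic analysis of
    stepwise chemical transformations studied by steered molecular dynamics.
    Provides Eyring transition-state-theory kinetics (equilibrium constants,
    forward and reverse rate constants, product lifetimes) from per-step
    activation and reaction free energies; composition of elementary steps
    into process and pathway free-energy profiles with rate-determining-step
    identification; Jarzynski-equality estimation of Gibbs free-energy
    differences from nonequilibrium work ensembles with bootstrap uncertainty;
    a toy steered Langevin-dynamics engine (Lennard-Jones 12-6-1 interactions,
    distance and distance-difference reaction coordinates, BAOAB integrator)
    that generates such work ensembles with known analytic ground truth; XYZ
    structure I/O with interatomic-distance reports; and bundled reference
    step-energetics tables for the water- and formic-acid-assisted
    adenine-to-guanine transition in gas and aqueous solution phases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
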