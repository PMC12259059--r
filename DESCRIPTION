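Package: condensr
Title: Coarse-Grained Simulation and Analysis of Protein-DNA Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A minimal coarse-grained model of protein-DNA biomolecular
    condensates: single-bead proteins and bead-spring DNA interacting through
    an Ashbaugh-Hatch (hydropathy-scaled Lennard-Jones) pair potential,
    evolved by Langevin dynamics with a velocity-Verlet (BAOAB) integrator.
    Includes system builders, trajectory I/O, and the full analysis suite for
    condensate studies: molecule-level clustering and largest-cluster
    composition, DNA radius of gyration and persistence length, DNA-bound
    protein fractions, radial density profiles with single- and double-tanh
    interface fits, coexistence concentrations, block averaging, and a
    multi-mode Gaussian decomposition of protein displacement distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
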