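Package: tbion
Title: Tightly Bound Ion Electrostatics for RNA 3D Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ion-correlation electrostatics for RNA 3D structures. Implements
    the tightly bound ion (TBI) model: Mg2+ ions in the strongly correlated
    layer near the RNA surface are treated by explicit enumeration of discrete
    binding modes over per-phosphate cells with Generalized Born solvation,
    while the remaining ion atmosphere is treated with a nonlinear
    Poisson-Boltzmann grid solver. Reports total electrostatic free energies
    and their components, per-nucleotide Mg2+/Na+ binding fractions, the most
    probable binding mode, and downstream folding-stability and ion-uptake
    quantities, with an idealized A-form helix generator for fixtures and
    intermediate-state proxies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
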