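Package: polytrans
Title: Langevin Dynamics of Polyelectrolyte Translocation Through a Nanopore
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained Langevin dynamics of a single charged bead-spring
    polymer threading through a membrane nanopore, with explicit counterions
    and salt, periodic Coulomb electrostatics by smooth Ewald summation, and
    a driving electric field confined to the pore channel. Includes the full
    analysis pipeline for translocation experiments: first-passage-time
    statistics and their scaling exponents in chain length and field
    strength, region-resolved chain conformation on normalized time,
    translocation-coordinate dynamics and its mean square displacement,
    Manning-style ion-condensation accounting, and spatial probability and
    density distributions, together with synthetic-data generators that make
    every analysis stage testable without running dynamics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
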