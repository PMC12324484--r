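Package: ligrest
Title: Ligand Geometry Restraints: Generation, Validation and Restrained
    Minimisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building crystallographic geometry restraints for
    small-molecule ligands and non-standard residues from a validated
    three-dimensional geometry. Reads and writes Chemical Component
    Dictionary style component CIF entries and the monomer-library
    restraint CIF dialect, perceives internal coordinates (bonds, angles,
    torsions with periodic or discrete ideal values, planes, chiral
    volumes) from the bond graph, assigns estimated standard deviations
    from user-supplied reference bond/angle distribution tables, validates
    geometries with a maximum-|Z| classification scheme with standard
    deviation floors, enumerates carboxylate protonation variants, trims
    polymerisation termini, and verifies restraint sets by restrained
    quasi-Newton re-minimisation with analytic gradients and a
    repulsive-only nonbonded term.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
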