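Package: oligoshift
Title: Oligomeric-State Analysis and Interface Engineering of Homomeric Enzyme Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining and engineering the oligomeric state of
    homomeric enzyme assemblies such as form II RuBisCO. Provides a tidy
    coordinate model for PDB structures, derivation and application of
    cyclic/dihedral symmetry definitions, interface contact, hydrogen-bond
    and salt-bridge atlases with geometric interface-residue criteria,
    theoretical small-angle X-ray scattering (SAXS) profiles by the Debye
    formula with Guinier analysis and chi fitting for oligomeric-state
    classification, a combinatorial interface-mutant design screen with a
    transparent surrogate interaction score, derived enzyme-kinetics
    quantities from the carboxylase/oxygenase specificity relation, and
    seeded synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
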