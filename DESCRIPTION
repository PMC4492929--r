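Package: saambe
Title: Predicting Binding Free Energy Changes of Protein-Protein Complexes upon Point Mutation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the SAAMBE (Single Amino Acid Mutation based change in
    Binding free Energy) scoring scheme for predicting the change in
    protein-protein binding free energy caused by single point mutations.
    Structure-derived knowledge-based terms (rotamer entropy, hydrophobicity,
    hydrogen bonds, interface areas from Shrake-Rupley solvent accessible
    surface areas) are combined with imported molecular-mechanics and
    Poisson-Boltzmann energy components in a weighted linear formula. Includes
    the probability-based small/large-effect mutation classifier, weight
    fitting by multiple linear regression with cross-validation and outlier
    trimming, a dielectric-constant scan harness, interface-location
    classification (core/support/rim/interior/surface), SKEMPI-style dataset
    curation, confusion-matrix benchmarking, and deterministic toy-complex and
    simulated-dataset generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
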