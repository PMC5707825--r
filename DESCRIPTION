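Package: rotaclash
Title: Rotamer-Based Steric Clash Prediction for Amino Acid Substitutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts whether an amino acid substitution can be sterically
    accommodated in a protein three-dimensional structure. Fast decision
    rules based on solvent accessibility and side-chain size are followed,
    where needed, by exhaustive fitting of backbone-dependent side-chain
    rotamers built from ideal internal coordinates and screened with a van
    der Waals overlap test against all surrounding heavy atoms, including
    ligands and cofactors. Ships a PDB reader/writer with the cleanup rules
    the method assumes, an internal Shrake-Rupley solvent accessibility
    implementation, a minimal embedded rotamer library, synthetic structure
    generators for offline testing, and confusion-matrix performance
    scoring with clash as the positive class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
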