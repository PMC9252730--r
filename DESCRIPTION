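Package: resibind
Title: Residue-Centric Prediction of Protein-Ligand Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts ligand binding-site residues from protein 3D
    structures. Each residue and its first two shells of spatial
    neighbors are encoded as a 42-value physicochemical descriptor
    vector (solvent accessibility, cysteine flag, six atom-class
    counts and six non-covalent interaction counts, averaged over the
    shells); residues are classified binding/non-binding by an
    ensemble of class-balanced extremely randomized trees trained on a
    local template store of ligand-bound structures; predicted
    residues are clustered into candidate pockets with DBSCAN and
    candidate ligands are ranked by a distance-signature site
    similarity score. Includes a synthetic-structure generator so the
    whole pipeline is testable without external databases, evaluation
    metrics (MCC, precision, recall, DCA), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
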