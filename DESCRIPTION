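Package: invdock
Title: Inverse Molecular Docking for Protein Target Fishing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for inverse virtual screening: a single small molecule is
    docked into a database of protein binding sites to prioritize candidate
    protein targets. Builds a binding-site database from PDB structures
    (ligand and residue distance filters, sequence clustering, site-similarity
    clustering, centroid sphere covers), docks ligands with a hierarchical
    fragment engine (atomic grid, knowledge-based pair potential, maximum-clique
    fragment linking, pose minimization), selects targets by a score-distribution
    threshold, profiles protein-ligand interactions geometrically, and validates
    screens with early-recognition metrics (ROC AUC, enrichment factors, RIE,
    BEDROC, predictiveness curve and standardized total gain). Includes seeded
    synthetic-fixture generators so the whole pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
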