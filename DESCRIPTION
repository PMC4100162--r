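Package: specsift
Title: Substrate-Specificity Profiling of Protease-Ligand Pose Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-docking analysis toolkit for substrate-specificity studies
    of papain-family (C1A) cysteine proteases, built around the maize
    cysteine protease 1 (zmCP1) active site.  Computes per-residue nine-bit
    structural interaction fingerprints (SIFt) for protein-ligand complexes,
    averages them over pose and ligand ensembles, and extracts consensus
    binding-site residues.  Validates docking poses by heavy-atom RMSD
    (with symmetry correction over ligand bond-graph automorphisms) and
    selects catalytically competent binding modes using subsite-occupancy,
    catalytic-distance and oxyanion-hole rules.  Ranks fluorogenic AMC
    substrate libraries from docking score tables, and performs MM-PBSA
    end-state binding free-energy bookkeeping over trajectory snapshots
    with polar/non-polar decomposition.  A synthetic-data module generates
    planted-interaction complexes, pose ensembles and energy series with
    known ground truth so every stage is testable without external
    structures or engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
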