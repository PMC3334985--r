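Package: sitemapr
Title: Site Mapping of Protein-Ligand Recognition from Docking Pose Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds per-residue interaction maps ("site maps") of
    protein-ligand recognition from ranked ensembles of docked ligand
    poses. Hydrogen-bond and van der Waals contacts are detected
    geometrically, tallied per protein residue over the top-ranked
    poses, normalized separately per interaction type, and the
    important residues are selected with dual cumulative-sum cutoffs.
    Map quality is scored against crystallographic contact sets
    (reproduction, correctness and their product), cutoffs can be
    optimized by grid scan, and docked poses are evaluated by RMSD.
    Dynamic site mapping aggregates maps over multiple receptor
    conformers and selects the conformer most similar to the
    ensemble-average map. Peptide mimicry of carbohydrate epitopes is
    quantified by fragmenting peptides into overlapping windows,
    pooling fragment maps, and comparing two site maps through a
    signed per-residue d-statistic. A synthetic-fixture generator
    produces toy binding sites and pose ensembles with programmed
    contact frequencies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
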