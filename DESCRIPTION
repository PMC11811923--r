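Package: nacsuite
Title: Near-Attack-Conformer and Active-Site Dynamics Analysis for Designer Enzymes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis toolkit for homodimeric designer
    enzymes built on the LmrR scaffold with a para-aminophenylalanine
    (pAF) catalytic residue. Reads single- and multi-model PDB coordinate
    files, measures near-attack-conformer (NAC) dihedral/distance
    statistics with pro-(R)/pro-(S) classification and Gaussian kernel
    density maps, estimates interface pocket volumes on a probe-excluded
    grid, computes quaternary-structure metrics (closest-atom distances,
    inter-helix angles), RMSD/RMSF/PCA trajectory diagnostics,
    hydrogen-bond occupancy with persistent/transient classification,
    arginine forward/backward conformer states, cation-pi geometry,
    pairwise-RMSD conformational clustering, and transition-state-theory
    bookkeeping of reaction-profile barriers and fold-rate changes. A
    seeded synthetic-data module generates helices, cavity shells and
    mixture-model trajectories with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
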