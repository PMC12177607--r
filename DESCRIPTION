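Package: orscreen
Title: Desk-Scale Structure Assessment and Chemical-Space Screening for
    Olfactory Receptor Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational core of an in silico olfactory
    receptor-odorant workflow: reading and writing multi-MODEL PDB
    coordinate files; rigid-body (Kabsch) superposition with the
    iterative-pruning RMSD protocol used to isolate conserved structural
    cores; ensemble observables (RMSD series, per-residue RMSF, radius of
    gyration); backbone dihedral and Ramachandran classification,
    bond/angle deviation counts, clashscore and Shrake-Rupley solvent
    accessible surface area; descriptor-matrix cleaning, Pearson
    correlation filtering, PCA, K-means clustering with cluster-number
    selection by AIC, BIC, silhouette, Davies-Bouldin and
    Calinski-Harabasz indices, and centroid-proximity representative
    ligand selection; statistical evaluation of docking-score tables
    (Kruskal-Wallis, Dunn's post hoc, ROC/AUC); and seeded synthetic
    generators (ideal helices, Gaussian-mixture descriptor sets,
    two-population score tables) so every analysis is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    bio3d,
    cluster,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
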