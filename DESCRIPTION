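Package: cavigrow
Title: Cavity-Conditioned De Novo Ligand Design, Authentication and
    Bioactivity Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for structure-guided small-molecule
    discovery on protein surfaces. Detects and scores surface cavities on a
    protein structure with a hydrogen-probe 3D grid, grows cavity-conditioned
    ligands de novo with a fragment genetic algorithm, partitions the grown
    ligands into high- and low-affinity binder classes by binding energy with
    statistical authentication (Kolmogorov-Smirnov, Anderson-Darling and
    Epps-Singleton tests over empirical distribution functions), trains
    graph-neural-network style classifiers (GCM, GCN, GAT, AFP encoders with a
    logistic readout) on the partition with stratified cross-validation and
    in-fold upsampling, and ranks screened compounds by ROC-threshold
    selection (G-means, Youden's J) plus personalized PageRank over
    bioactivity descriptor spaces. Includes deterministic synthetic-fixture
    generators (toy pockets, planted energy mixtures, separable scaffold
    families) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    bio3d,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
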