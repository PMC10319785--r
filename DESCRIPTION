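Package: graphccs
Title: Collision Cross Section Prediction from Molecular Graphs with
    Edge-Conditioned Graph Convolutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts ion-mobility collision cross section (CCS) values of
    small molecules from 3D-conformer-derived molecular graphs using an
    edge-conditioned graph convolutional network with adduct-type fusion.
    Provides the full workflow: SMILES parsing and 3D conformer generation
    (distance-geometry embedding plus MMFF94 minimisation via Open Babel),
    molecular graph featurisation, network training with Adam, dataset
    curation and splitting, evaluation metrics, masking-based feature
    importance, rotation-robustness analysis, learned-representation export,
    and multidimensional (m/z, retention time, CCS) candidate filtering for
    compound identification. Includes a synthetic-data generator with a
    deterministic projection-approximation CCS oracle for download-free
    testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    MASS,
    Matrix,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
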