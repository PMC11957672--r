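Package: resibind
Title: Binding-Residue Prediction with Graph Neural Networks on Residue
    Contact Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts, for every residue of a protein, binding to three
    ligand classes (metal ions, nucleic acids, small molecules) from
    pre-computed protein-language-model embeddings and a predicted 3D
    structure. The structure enters only as a distance-thresholded
    C-alpha residue graph with distance-derived edge weights, on which
    lightweight graph neural networks (GraphSAGE, GCN, GATv2 variants)
    perform message passing. Includes DSSP feature normalization,
    class-weighted multi-label training with 5-fold cross-training,
    confusion-matrix metrics with per-protein confidence intervals, and
    a fully synthetic fixture generator so the entire pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
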