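Package: patchbind
Title: Structural Surface-Patch Features for RNA-Binding Residue Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts RNA-binding residues of proteins from structure.
    Residues are reduced to a five-point shape descriptor (backbone N, CA,
    C, O plus the side-chain center), surface patches of two or three
    residues are compared by a permutation-minimized rigid least-squares
    distance, template patches drawn from known binding sites are grouped
    by complete-linkage clustering into medoid representative patches, and
    each surface residue is encoded by its accumulated distances to the
    representatives together with PSSM conservation scores and an
    interface propensity. An ensemble of ridge regression, perceptron and
    multilayer-perceptron members scores residues in [-1, 1] under
    protein-level cross-validation. Includes a synthetic complex generator
    so the full pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    nnet,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    Biostrings,
    yaml,
    optparse,
    pROC
Config/testthat/edition: 3
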