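Package: triNetPath
Title: Path-Based miRNA-Disease Association Prediction on a
    miRNA-Drug-Disease Three-Layer Heterogeneous Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts microRNA-disease associations by fusing reconstructed
    miRNA-disease, miRNA-drug and drug-disease bipartite networks with miRNA
    functional, drug chemical and MeSH-derived disease semantic similarity
    networks into a three-layer heterogeneous network, and scoring
    miRNA-disease pairs through direct and drug-mediated network paths
    penalized by a path-length decay exponent. Includes MeSH tree-number
    disease semantic similarity (two semantic models, fused),
    similarity-propagated bipartite network reconstruction with threshold
    pruning, length-2 path scoring, five-fold and global leave-one-out
    cross-validation with rank-based AUC, parameter sweeps, and a planted
    block-structure synthetic network generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, pROC, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
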