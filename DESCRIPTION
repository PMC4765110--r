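Package: OrthoSieve
Title: Machine-Learning Filtering of False-Positive Homology Clusters
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies putative homology clusters (multiple sequence
    alignments of proteins grouped by heuristic orthology tools) as true
    homology or false-positive non-homology. Provides transitive-closure
    assembly of clusters from pairwise orthology relations, a progressive
    protein aligner, ten alignment-level cluster features including a
    Monte-Carlo sliding-window alignment-randomness score, a generative
    simulator of ground-truth training clusters (random draws and WAG+I
    sequence evolution on random binary trees), and a zoo of base
    classifiers combined by stacking meta-classifiers for cluster
    filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    igraph,
    nnet,
    e1071,
    randomForest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
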