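Package: drpclust
Title: Structural Clustering of Disulfide-Rich Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Clusters disulfide-rich peptides (DRPs) by structural
    similarity. Implements an iterative rigid-body structure aligner with
    native-overlap and sequence-identity metrics, a disulfide-bond
    equivalence distance that enumerates all bond mappings and cysteine
    orientations, average-linkage agglomerative clustering with cutoff
    termination, a five-step clustering pipeline (filtering, native-overlap
    clustering, knottin reclustering by disulfide distance, and two
    singleton-reassignment passes), representative selection, per-cluster
    sum-of-pairs conservation scoring with BLOSUM62, and a synthetic
    peptide-structure generator for fully reproducible benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
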