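Package: spectree
Title: Spectral Disk-Covering Phylogeny Reconstruction from Gene Orders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-parsimony phylogeny reconstruction for gene-order data
    (signed permutations) under inversion distance. Implements the
    Hannenhalli-Pevzner reversal distance, an exact branch-and-bound
    inversion median solver with a budgeted greedy fallback, a spectral
    disk-covering method that recursively bipartitions genomes with the
    Fiedler vector of the random-walk graph Laplacian (with an
    overlap-aware refinement and a big-overlap avoidance heuristic), and
    merging algorithms that reassemble sub-topologies into a full tree.
    Includes simulators for uniform-random and birth-death model trees with
    inversion evolution, and topological accuracy metrics (false
    positive/negative internal edges) against model trees.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
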