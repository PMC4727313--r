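Package: tieclust
Title: Tie-Aware Hierarchical Clustering and Cluster Frequency Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agglomerative hierarchical clustering that takes ties in
    proximity seriously: instead of breaking equidistances arbitrarily, it
    enumerates every distinct dendrogram reachable by resolving the ties in
    all possible ways.  Four cluster-contrast functions (graph, relaxed
    graph, set and relaxed set) measure whether, and to what extent, a query
    cluster occurs in a dendrogram, and a frequency estimator averages the
    contrasts over any set of dendrograms sharing one leaf set, yielding an
    empirical probability of each cluster.  Includes the analytic
    equidistant (maximal-tie) results, a brute-force topology enumerator,
    deterministic synthetic-data generators, Newick input/output and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
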