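Package: pknfilter
Title: Expression-Filtered Prior-Knowledge Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Filters a directed prior-knowledge reference network (signaling
    reactions or enzyme-centered metabolism) onto the set of genes detected in
    tag-count expression data, in a strict and a k-extended variant, and
    validates the resulting subnetworks. Pathway over-representation is tested
    with a noncentral hypergeometric (biased-urn) null whose odds derive from
    tissue-panel expression intensities, with Monte-Carlo empirical p-values
    for the extended networks and Storey q-value false discovery rate control.
    Key nodes are scored by the pairwise disconnectivity index and its
    filtering-induced change, and network structure is summarised by bow-tie
    decomposition and a differential-expression variance analysis. A seeded
    synthetic-data generator emulates all required inputs at realistic scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    optparse
Config/testthat/edition: 3
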