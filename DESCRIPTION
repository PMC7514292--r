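Package: corehub
Title: Effective Connectivity, Connective-Core Hubs and EEG Microstate Complexity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates directed effective-connectivity networks from
    multichannel recordings with normalized transfer entropy (surrogate
    bias subtraction and conditional-entropy normalization), identifies
    connective-core hubs from windowed betweenness centrality with a
    per-node rank test, classifies hubs as divergent, convergent or
    neutral from their net entropy, quantifies core composition,
    resilience (characteristic-path-length impact of node removal) and
    preservation across conditions (homogeneity and heterogeneity),
    tracks hub dynamics in sliding windows with peak triggering, and
    segments EEG into four microstates whose label sequences are scored
    with quaternary Lempel-Ziv complexity. Includes seeded generators
    for coupled autoregressive networks with planted hub structure and
    for template-driven microstate EEG, used as ground truth throughout
    the test suite.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    signal,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
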