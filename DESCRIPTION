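Package: swipenet
Title: Directed Two-Mode Network Analysis of Swipe-Based Dating Markets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing directed two-mode (bipartite) networks in
    which ties may only run between two node classes but carry direction,
    as in heterosexual swipe-based dating markets where users express
    interest in members of the opposite gender. The network is represented
    by a pair of incidence matrices, one per sending mode. Provides
    adapted whole-network descriptives (density, per-mode indegree
    centralization, reciprocity, standardized degrees), tie-level
    desirability-gap statistics, conditional uniform graph (CUG)
    permutation tests based on within-row permutation of both incidence
    matrices (all-ties, outdegree-weighted, and reciprocated-only
    variants), a two-sample randomization test with Cohen's d for
    cross-mode desirability comparison, data-cleaning filters (active
    users, indiscriminate-reciprocator bots, city segmentation), a
    synthetic two-sided market generator with tunable aspirational
    pursuit and desirability-gap-dependent reciprocation, and a command
    line interface producing publication-style summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
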