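Package: aspiradyn
Title: Aspiration Dynamics and Strategy Success on Weighted Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evolutionary 2x2 games on weighted undirected networks
    under aspiration-based (self-evaluation) update rules. Provides exact
    finite-population analysis: the full 2^N strategy Markov chain, its
    stationary distribution, and a first-order weak-selection perturbation
    yielding the strategy-success condition (risk dominance a+b > c+d for
    symmetric aspirations, and its shift under strategy-contingent
    aspirations), together with structure-coefficient extraction, exhaustive
    enumeration of small connected graphs, imitation-based comparison
    dynamics (pairwise comparison and death-birth with mutation), and a
    compiled Monte Carlo simulator for large networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
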