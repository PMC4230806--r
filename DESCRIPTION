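Package: bnsteady
Title: Exact Steady-State Analysis of Boolean Molecular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes all steady states (synchronous fixed points) of Boolean
    network models of molecular regulatory systems. Any Boolean network is
    first rewritten as an AND-NOT network whose steady states project onto
    those of the original model, the signed wiring diagram is then reduced by
    steady-state-preserving motif rules, and the remaining fixed-point
    conditions are solved exactly as a square-free polynomial system over
    GF(2) using a lexicographic Groebner basis with back-substitution.
    Removed variables are reconstructed by backtracking. Includes two
    independent verification oracles (exhaustive state-space enumeration and
    feedback-vertex-set candidate enumeration), seeded generators for
    Kauffman N-K and power-law in-degree benchmark networks, and readers and
    writers for plain-text rule files, BoolNet-style tables, and SIF/DOT
    interaction graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
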