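Package: treediet
Title: Treewidth Reduction of Graphs by Minimal Edge Loss over Tree Decompositions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Thins a given tree decomposition of a graph down to a prescribed
    smaller width (a "tree diet") while losing a minimum number, or minimum
    total weight, of graph edges. Implements the green/orange/red coloring
    dynamic program over rooted tree decompositions, a specialization to path
    decompositions via d-simple colorings, elimination-ordering heuristics
    (min-degree, min-fill) for building decompositions, PACE-style .gr/.td
    input and output, RNA secondary-structure front-ends (dot-bracket, bpseq)
    with backbone-aware edge weighting, exact brute-force reference solvers,
    and seeded instance generators for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
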