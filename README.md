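# treediet

Treewidth reduction of graphs by minimal edge loss over tree decompositions.

Dynamic programs over tree decompositions power many exact methods in
structural bioinformatics — RNA structure–sequence alignment, constraint
sampling for negative design, motif search — but their cost grows
exponentially with the decomposition width. Pseudoknotted RNA structure
graphs routinely have width 4 or more, which puts exact runs out of reach.

`treediet` implements the *tree diet*: given a graph *G* and a tree
decomposition of width *tw*, remove vertices from the decomposition's bags
until every bag fits the prescribed target width *tw′*, while losing a
minimum number (or minimum total weight) of graph edges. An edge is *lost*
when no bag retains both endpoints; the thinned decomposition is a valid
decomposition of the kept-edge subgraph and can be fed to any
downstream width-parameterized algorithm at the cheaper width.

The optimizer colors every occurrence of a vertex **green** (kept),
**orange** (removed here, possibly kept below) or **red** (removed in the
whole subtree), under local rules that force each vertex's green
occurrences to form a connected subtree. With the decomposition rooted at
an empty bag, the table cell *c(X, f)* stores the best weight of edges
realizable strictly below bag *X* under bag coloring *f* (−∞ if *f* keeps
more than *tw′* + 1 vertices green), and the recurrence maximizes over
orange-to-child assignments and compatible child colorings, counting each
realizable edge at the link entering the root of its green subtree. The
optimum is read at the empty root; a traceback reconstructs the coloring,
the thinned decomposition, and the manifest of lost edges. A
specialization to path decompositions enumerates only *d-simple* states
(at most *d* orange and *d* red per bag, *d* = *tw* − *tw′*) without losing
optimality.

The package also provides PACE-style `.gr`/`.td` I/O, RNA front-ends
(dot-bracket with pseudoknots, bpseq) with backbone-aware weighting,
elimination-ordering heuristics (min-degree, min-fill, lex-BFS) for
building decompositions, binarization, exact brute-force references, and
seeded instance generators used by the property-based test suite.

## Worked example

Thin a pseudoknotted 10-nucleotide structure graph (two crossing helices,
13 edges of which 9 are backbone) from width 3 to width 2 while protecting
the backbone:

```r
library(treediet)

g <- random_pseudoknot_graph(10, n_helices = 2, helix_len = 2,
                             crossing_prob = 0.5, seed = 7005)
graph_summary(g)
#> $n          [1] 10
#> $m          [1] 13
#> $m_backbone [1] 9

td <- heuristic_decomposition(g, "min-fill", seed = 5)
decomposition_width(td)
#> [1] 3

res <- tree_diet(g, root_with_empty_bag(td),
                 diet_params(2, "count", backbone_protect = TRUE))
res
#> <diet_result> width 3 -> 2: 11/13 edges kept, 2 lost (0 backbone)
res$lost_edges
#>   u v weight backbone
#> 2 1 7      1    FALSE
#> 8 4 9      1    FALSE
decomposition_width(res$thinned)
#> [1] 2
```

The diet reaches width 2 by sacrificing two base-pair edges (1–7 and 4–9)
and keeps the entire backbone: downstream algorithms can now run with
bag size 3 instead of 4, and only those two pairs need a countermeasure.
When no backbone-preserving diet exists at the requested width, the result
lists the casualties in `lost_backbone` and raises a warning instead of
failing.

The same pipeline is available from the shell via the launcher installed
at `inst/cli/treediet`:

```sh
treediet diet --graph structure.dbn --target 3,2 --out-dir out/
treediet decompose --graph graph.gr --method min-fill --seed 1 --out graph.td
treediet validate --graph graph.gr --td graph.td
```

`diet` writes, per target width, the thinned `.td`, a TSV manifest of lost
edges, and a JSON report (widths, edge counts, lost weight, seed, input
hashes). Exit code 3 flags backbone edges lost despite protection.

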