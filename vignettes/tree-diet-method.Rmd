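---
title: "Thinning tree decompositions by minimal edge loss: the method behind treediet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thinning tree decompositions by minimal edge loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treediet)
```

## The problem

Many algorithms on graphs — RNA structure–sequence alignment, constraint
sampling for sequence design, and other dynamic programs over tree
decompositions — run in time exponential in the *treewidth* of their input
graph. For pseudoknotted RNA structure graphs (backbone path plus base-pair
edges) the treewidth is often 4 or more, which makes exact runs
prohibitively slow or memory-hungry.

`treediet` implements a pragmatic preprocessing step: given a graph $G$ and
a tree decomposition $\mathcal{T}$ of width $tw$, remove vertices from the
*bags* of $\mathcal{T}$ until every bag has at most $tw'+1$ vertices, so
that the decomposition has a prescribed smaller width $tw'$. Removing a
vertex from a bag can make some edges invisible: an edge is *visible* if
some bag contains both endpoints, otherwise it is *lost*. The optimization
problem — the *tree diet* — is to reach the target width while losing a
minimum number (or minimum total weight) of edges. The thinned
decomposition is then a valid decomposition of the subgraph of kept edges,
and downstream algorithms can run on it at the cheaper width, with
downstream-specific countermeasures for the few lost edges.

Note that this is deliberately *not* the harder problem of finding the best
width-$tw'$ decomposition over all decompositions (edge deletion to bounded
treewidth); the diet is constrained to thin the decomposition it is given,
which is what makes it tractable.

## The coloring dynamic program

The search space is expressed as colorings of vertex *occurrences*. Every
occurrence of a vertex in a bag gets one of three colors:

* **green** — the vertex stays in this bag;
* **orange** — removed here, but may still be kept somewhere below;
* **red** — removed from this bag and its entire subtree.

With the decomposition rooted at an empty bag, a coloring is valid when,
along every parent→child link: a vertex absent from the parent enters green
or orange (R1); a green vertex stays green or turns red (R2); a red vertex
stays red (R3); and an orange vertex is orange or green in exactly one
child that contains it, red in the others (R4). These rules force the green
occurrences of each vertex to form a connected subtree, so deleting all
non-green occurrences yields a valid decomposition of the *realizable*
edges — those whose endpoints are green together in some bag. Diets and
valid colorings are interchangeable: an optimal diet is an optimal valid
coloring with at most $tw'+1$ green vertices per bag.

The table cell $c(X, f)$ holds, for bag $X$ and bag coloring $f$, the best
total weight of edges realizable strictly below $X$ ($-\infty$ if $f$ has
more than $tw'+1$ greens). The recurrence maximizes over assignments of
$f$'s orange vertices to children (rule R4's "exactly one child") and over
child colorings compatible with the per-vertex cases above, adding for each
link the weight of edges whose endpoints are both green in the child but
not both green in the parent bag. Every realizable edge is counted at
exactly one link — the one entering the root of its green subtree — so the
optimum appears at the empty root and a traceback reconstructs a globally
valid coloring. The state count is at most $\sum_{\text{bags}} 3^{|X|}$
(instrumented and asserted in the tests); running time additionally scales
with $\Delta^{tw+2}$ where $\Delta$ is the maximum child count, which is
why the driver suggests binarizing decompositions with $\Delta > 2$.

Implementation notes:

* Rather than enumerating `(parent coloring, child coloring)` pairs
  directly, the engine groups child colorings by their restriction to the
  shared vertex set $S = X \cap Y$ and precomputes, per restriction and per
  orange-assignment pattern, the best child value. A parent state then
  needs only a table lookup (single-child bags are fully vectorized; bags
  with several children loop over the small set of orange-assignment maps).
* Ties are broken deterministically: child colorings are enumerated in a
  canonical order (vertices sorted, colors ordered g < o < r, first vertex
  most significant) and the first optimum is kept, first within a shared
  restriction, then across restrictions, then across assignment maps.
  Reruns are byte-identical. The specific tie-break order is a design
  choice; any fixed order gives a valid optimal diet.
* $-\infty$ is IEEE `-Inf`; sums saturate naturally and the root value is
  always finite because the coloring that keeps nothing (orange at each
  top occurrence, red below) is feasible for every target $\ge -1$.

## Path decompositions and d-simple colorings

On a path decomposition rooted at one end, an optimal $d$-diet (with $d$
the width reduction) can always be found among *d-simple* colorings: at
most $d$ orange and $d$ red vertices per bag. `path_diet()` therefore
enumerates only those states, shrinking the per-bag state space from
$3^{|X|}$ to $O(|X|^{2d})$, and provably returns the same objective as the
general program — the test suite checks the three-way agreement with the
unrestricted DP and the brute-force reference on every random path
instance. The bound is tight: the suite contains a constructed weighted
instance whose unique optimum must delete two vertices (one orange, one
red) from the central bag, and verifies that restricting to one removal
per bag is strictly worse. When $d$ is derived as input width minus target
width, a bag of size $s \le tw+1$ needs $s - tw' - 1 \le 2d$ removals, so
the $d$-simple space is never infeasible; a defensive fallback to the
general program exists nonetheless and reports itself via a message.

## Weights and backbone protection

Two objective modes exist: `count` treats every edge as weight 1; `weight`
maximizes the total weight of realizable edges. For RNA structure graphs
the backbone edges (consecutive nucleotides) should survive thinning
whenever possible: with `backbone_protect = TRUE` every backbone edge is
re-weighted to (sum of non-backbone weights) + 1 before optimizing, so any
diet keeping one more backbone edge beats any diet that trades it for all
remaining pair edges. Protection is a weighting scheme, not a hard
constraint: for some instances no backbone-preserving diet exists at the
requested width, in which case the lost backbone edges are listed in
`lost_backbone` and a warning (CLI: exit code 3) is raised rather than an
error. The reported `objective` is always on the scale of the weights that
were optimized, so the conservation identity `objective + lost weight =
total weight` holds exactly in every mode.

## Decomposition utilities

* `heuristic_decomposition()` builds decompositions from greedy
  elimination orderings (min-degree, min-fill, or reverse lex-BFS): the
  eliminated vertex plus its current neighborhood forms a bag, the
  neighborhood is made a clique, and each bag links to the bag of its
  first-eliminated neighbor. Ties between candidate vertices are broken by
  a seeded uniform choice, recorded in the output attributes, so runs are
  reproducible despite the heuristics being under-specified. The width
  obtained is an upper bound on the treewidth; the suite compares it
  against `exhaustive_treewidth()` (exact, $n \le 8$, subset dynamic
  program over eliminated sets) on small graphs.
* `root_with_empty_bag()` appends a fresh empty root (or reuses the
  smallest-id empty bag, making the operation idempotent); it never
  changes the width or the visible/lost edge sets.
* `binarize()` replaces a bag with $c > 2$ children by a chain of $c-1$
  copies, each keeping at most two children. Width and per-vertex
  connectivity are preserved, and because the copies may be thinned
  *differently*, the optimal diet of the binarized decomposition never
  loses more edges than that of the original — an inequality the
  acceptance suite checks on every generated instance. The chain layout is
  this package's choice among the valid duplication schemes.

## Synthetic instance families

The generators define the study conditions for all tests:

* `random_instance(n, edge_prob, seed)` — Erdős–Rényi graphs (the suite
  uses $n \in [4,8]$, edge probability 0.4) with min-fill decompositions;
  small enough that the independent brute-force reference
  (`brute_force_tree_diet`, exhaustive over per-vertex connected retained
  bag sets with capacity pruning) is exact ground truth.
* `random_path_instance()` — interval models: each vertex gets a random
  interval over a path of bags, edges are sampled among co-occurring
  pairs; valid path decompositions by construction.
* `random_regular_multipartite()` + `clique_reduction_gadget()` — the
  hardness-reduction construction turned into a test-instance factory: a
  1-diet of the gadget loses at most $L = \delta k - \binom{k}{2}$ edges
  exactly when the multipartite input has a $k$-clique. Generated at
  $k \in \{2,3\}$ and part sizes 2–3 so the dynamic program (not the
  brute-force oracle) is the solver under test, checked against an
  exhaustive clique search.
* `random_pseudoknot_graph(L, n_helices, helix_len, crossing_prob, seed)`
  — backbone path plus stacked helices on disjoint blocks; adjacent
  helices swap partners with probability `crossing_prob`, creating
  pseudoknots. Crossing-free outputs are outerplanar (treewidth ≤ 2,
  asserted against the exact solver). The backbone-protection experiment
  uses $L = 10$, two helices of two pairs, crossing probability 0.5, and
  keeps the fixtures whose brute-force certificate proves a
  backbone-preserving diet exists at the target width.

These generators emulate the *shape* of real inputs (sparse graphs,
interval structure, backbone + crossing pairs) at deliberately small sizes
where exhaustive references are available. Passing tests therefore
demonstrate exactness of the optimization on its full small-instance
domain and the structural laws on gadget families; they do not measure
alignment quality, design success rates, or runtime behavior on
chromosome-scale inputs.

## Numerical and degenerate-input choices

* Target width $-1$ is allowed and empties every bag (everything lost);
  targets at or above the input width are no-op successes, not errors.
* Degenerate decompositions (no bags, a single empty bag) have width $-1$
  by the "largest bag minus one" convention and are accepted everywhere.
* A base pair between backbone-adjacent positions merges into the backbone
  edge (backbone flag wins, larger weight kept), because the unordered
  vertex pair is the edge key.
* An input decomposition wider than necessary is accepted as-is; the diet
  only ever narrows the given decomposition.
* Vertices that lose all green occurrences are reattached as singleton
  bags under the root, so the thinned decomposition always covers every
  vertex; after reattachment the width is at most $\max(tw', 0)$.

## Problem sizes used by the test and acceptance runs

The randomized suites use 300 general instances ($n \le 8$), 200 path
instances, 100 binarization instances (child counts up to 5), 100
certified pseudoknot fixtures, and the gadget/single-bag/caterpillar
families described above — sizes chosen so each family runs in a couple of
minutes while the exhaustive references remain exact.

## Known limitations

* The brute-force reference guards at ~26 vertex occurrences and 64 bags;
  it is a test oracle, not a solver.
* `exhaustive_treewidth()` is limited to $n \le 8$.
* The package never searches over decompositions: a poor input
  decomposition yields a poor (though optimal-for-it) diet. Results on
  the same graph can differ across heuristics and seeds.
* Running time grows as $3^{tw}$ in the input width; widths much beyond
  ~12 (bag size 13) are impractical in this R implementation.
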