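#' Build a tree decomposition from an elimination ordering heuristic
#'
#' Runs a greedy elimination ordering over the graph: repeatedly pick a
#' vertex, make its current neighborhood a clique, and record the bag
#' `{vertex} + neighbors`. Bags are linked by attaching each bag to the bag
#' of the first-eliminated vertex of its neighborhood, which yields a valid
#' tree decomposition whose width upper-bounds the treewidth.
#'
#' Methods: `"min-degree"` picks a vertex of minimum current degree,
#' `"min-fill"` one whose elimination adds the fewest fill edges, and
#' `"lex-bfs"` eliminates in reverse lexicographic-BFS order. Ties are broken
#' by a seeded uniform choice so runs are reproducible.
#'
#' @param g a [diet_graph()].
#' @param method one of `"min-degree"`, `"min-fill"`, `"lex-bfs"`.
#' @param seed integer seed for tie-breaking.
#' @return A [tree_decomposition()] with attributes `method`, `seed`,
#'   `elimination_order` (vertex labels).
#' @export
heuristic_decomposition <- function(g, method = c("min-degree", "min-fill", "lex-bfs"),
                                    seed = 1L) {
  stopifnot(inherits(g, "diet_graph"))
  method <- match.arg(method)
  n <- length(g$vertices)
  if (n == 0) return(tree_decomposition())
  adj <- lapply(graph_adjacency(g), unique)
  order_idx <- with_seed(seed, elimination_order(adj, n, method))
  bags <- vector("list", n)
  parent <- integer(n)
  pos <- integer(n); pos[order_idx] <- seq_len(n)
  alive <- rep(TRUE, n)
  for (step in seq_len(n)) {
    v <- order_idx[step]
    nb <- adj[[v]][alive[adj[[v]]]]
    bags[[step]] <- g$vertices[c(v, sort(nb))]
    parent[step] <- if (length(nb) > 0) min(pos[nb]) else n
    # clique-ify the neighborhood, drop v
    for (u in nb) adj[[u]] <- setdiff(unique(c(adj[[u]], nb)), c(u, v))
    alive[v] <- FALSE
  }
  links <- if (n > 1) cbind(seq_len(n - 1), parent[seq_len(n - 1)]) else NULL
  td <- tree_decomposition(stats::setNames(bags, seq_len(n)), links)
  attr(td, "method") <- method
  attr(td, "seed") <- as.integer(seed)
  attr(td, "elimination_order") <- g$vertices[order_idx]
  td
}

elimination_order <- function(adj, n, method) {
  if (method == "lex-bfs") return(rev(lex_bfs_order(adj, n)))
  alive <- rep(TRUE, n)
  out <- integer(0)
  for (step in seq_len(n)) {
    cand <- which(alive)
    score <- vapply(cand, function(v) {
      nb <- adj[[v]][alive[adj[[v]]]]
      if (method == "min-degree") return(length(nb))
      # min-fill: non-adjacent pairs among the neighborhood
      fills <- 0L
      if (length(nb) >= 2) {
        for (a in seq_len(length(nb) - 1)) {
          fills <- fills + sum(!(nb[(a + 1):length(nb)] %in% adj[[nb[a]]]))
        }
      }
      fills
    }, numeric(1))
    v <- pick_one(cand[score == min(score)])
    nb <- adj[[v]][alive[adj[[v]]]]
    for (u in nb) adj[[u]] <- setdiff(unique(c(adj[[u]], nb)), c(u, v))
    alive[v] <- FALSE
    out <- c(out, v)
  }
  out
}

lex_bfs_order <- function(adj, n) {
  labels <- rep(list(integer()), n)
  visited <- rep(FALSE, n)
  out <- integer(0)
  for (step in seq_len(n)) {
    cand <- which(!visited)
    # lexicographically largest label wins; ties seeded
    best <- cand[1]; bestset <- cand[lex_ge(labels, cand)]
    v <- pick_one(bestset)
    visited[v] <- TRUE
    out <- c(out, v)
    for (u in adj[[v]]) if (!visited[u]) labels[[u]] <- c(labels[[u]], step)
  }
  out
}

# candidates whose label is lexicographically maximal: earlier visit steps
# rank higher, and an extended label beats its prefix (numeric comparison,
# independent of string collation)
lex_ge <- function(labels, cand) {
  bi <- 1L
  for (t in seq_along(cand)[-1]) {
    if (lex_cmp(labels[[cand[t]]], labels[[cand[bi]]]) > 0L) bi <- t
  }
  vapply(seq_along(cand), function(t)
    lex_cmp(labels[[cand[t]]], labels[[cand[bi]]]) == 0L, logical(1))
}

lex_cmp <- function(a, b) {
  k <- min(length(a), length(b))
  if (k > 0) for (t in seq_len(k)) {
    if (a[t] < b[t]) return(1L)        # earlier step: a ranks higher
    if (a[t] > b[t]) return(-1L)
  }
  if (length(a) > length(b)) return(1L)
  if (length(a) < length(b)) return(-1L)
  0L
}
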