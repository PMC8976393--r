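# small graph constructors and independent exhaustive checkers used as
# second opinions next to the package's own solvers

make_cycle <- function(n) {
  diet_graph(as.character(seq_len(n)),
             data.frame(u = as.character(seq_len(n)),
                        v = as.character(c(2:n, 1))))
}

make_complete <- function(n) {
  p <- utils::combn(n, 2)
  diet_graph(as.character(seq_len(n)),
             data.frame(u = as.character(p[1, ]), v = as.character(p[2, ])))
}

make_path_graph <- function(n) {
  diet_graph(as.character(seq_len(n)),
             if (n >= 2) data.frame(u = as.character(seq_len(n - 1)),
                                    v = as.character(2:n)) else NULL)
}

make_circulant <- function(n, shifts) {
  eu <- ev <- integer(0)
  for (s in shifts) for (a in seq_len(n)) {
    b <- (a + s - 1L) %% n + 1L
    eu <- c(eu, min(a, b)); ev <- c(ev, max(a, b))
  }
  e <- unique(data.frame(u = as.character(eu), v = as.character(ev)))
  diet_graph(as.character(seq_len(n)), e)
}

graph_is_connected <- function(g) {
  n <- length(g$vertices)
  if (n <= 1) return(TRUE)
  adj <- treediet:::graph_adjacency(g)
  seen <- 1L; frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- setdiff(unlist(adj[frontier]), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  length(seen) == n
}

# independent caterpillar test: acyclic and, per component, pruning leaves
# leaves a graph of maximum degree <= 2 (uses raw degree arithmetic only)
caterpillar_check <- function(edges_u, edges_v, vertices) {
  n <- length(vertices)
  m <- length(edges_u)
  if (m == 0) return(TRUE)
  iu <- match(edges_u, vertices); iv <- match(edges_v, vertices)
  # union-find acyclicity
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  comp <- n
  for (k in seq_len(m)) {
    ru <- find(iu[k]); rv <- find(iv[k])
    if (ru == rv) return(FALSE)
    parent[ru] <- rv; comp <- comp - 1
  }
  deg <- tabulate(c(iu, iv), n)
  spine <- which(deg >= 2)
  for (v in spine) {
    nb <- c(iv[iu == v], iu[iv == v])
    if (sum(nb %in% spine) > 2) return(FALSE)
  }
  TRUE
}

# exhaustive spanning-caterpillar search over all (n-1)-edge subsets
has_spanning_caterpillar <- function(g) {
  n <- length(g$vertices); m <- nrow(g$edges)
  if (m < n - 1) return(FALSE)
  combs <- utils::combn(m, n - 1)
  for (c in seq_len(ncol(combs))) {
    rows <- combs[, c]
    if (caterpillar_check(g$edges$u[rows], g$edges$v[rows], g$vertices))
      return(TRUE)        # acyclic with n-1 edges on n vertices = spanning tree
  }
  FALSE
}

# exhaustive induced-edge maximization over k-subsets
max_induced_edges <- function(g, k) {
  n <- length(g$vertices)
  max(apply(utils::combn(n, k), 2, function(X) {
    idx <- g$vertices[X]
    sum(g$edges$u %in% idx & g$edges$v %in% idx)
  }))
}

has_k_clique <- function(g, k) max_induced_edges(g, k) == choose(k, 2)

# sum of per-link count sets for a coloring, plus a double-counting check
count_set_accounting <- function(g, rtd, coloring) {
  total <- 0
  seen_keys <- character(0)
  dup <- FALSE
  for (key in names(rtd$bags)) {
    p <- rtd$parent[[key]]
    if (is.na(p)) next
    cs <- count_set(g, rtd$bags[[as.character(p)]],
                    coloring[[as.character(p)]],
                    rtd$bags[[key]], coloring[[key]])
    k <- treediet:::edge_keys(cs)
    if (any(k %in% seen_keys)) dup <- TRUE
    seen_keys <- c(seen_keys, k)
    total <- total + nrow(cs)
  }
  list(total = total, keys = seen_keys, duplicated = dup)
}

# weighted path instance whose optimum must delete two vertices from the
# central bag (the unavoidable case for d-simple colorings)
two_removal_instance <- function() {
  g <- diet_graph(c("z1", "z2", "a", "x", "y", "w", "p", "q", "e"),
                  data.frame(u = c("z1", "x", "w", "w", "p", "z2"),
                             v = c("a", "y", "z1", "z2", "q", "e"),
                             weight = c(5, 5, 1, 1, 5, 5)))
  td <- tree_decomposition(list("1" = c("z1", "a"), "2" = c("z1", "x", "y"),
                                "3" = c("z1", "z2", "w"),
                                "4" = c("z2", "p", "q"), "5" = c("z2", "e")),
                           cbind(1:4, 2:5))
  list(graph = g, td = td)
}
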