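#' Random graph plus heuristic decomposition
#'
#' Erdős–Rényi-style graph G(n, p) with a valid heuristic tree
#' decomposition, fully reproducible from the seed.
#'
#' @param n number of vertices (>= 1).
#' @param edge_prob edge probability in `[0, 1]`.
#' @param seed integer seed.
#' @param method heuristic passed to [heuristic_decomposition()].
#' @return A list with elements `graph` and `td`.
#' @export
random_instance <- function(n, edge_prob, seed, method = "min-fill") {
  stopifnot(n >= 1, edge_prob >= 0, edge_prob <= 1)
  g <- with_seed(seed, {
    pairs <- if (n >= 2) utils::combn(n, 2) else matrix(integer(), nrow = 2)
    keep <- stats::runif(ncol(pairs)) < edge_prob
    diet_graph(as.character(seq_len(n)),
               if (any(keep))
                 data.frame(u = as.character(pairs[1, keep]),
                            v = as.character(pairs[2, keep]))
               else NULL)
  })
  list(graph = g, td = heuristic_decomposition(g, method, seed = seed))
}

#' Random path-decomposition instance
#'
#' Gives every vertex a random interval over a path of bags (an interval
#' model), then samples graph edges among pairs that co-occur in some bag,
#' so the result is a valid path decomposition by construction.
#'
#' @param n number of vertices.
#' @param n_bags number of bags on the path.
#' @param max_span largest interval length per vertex.
#' @param edge_prob probability of keeping each co-occurring pair as an edge.
#' @param seed integer seed.
#' @return A list with elements `graph` and `td` (a path decomposition).
#' @export
random_path_instance <- function(n, n_bags, max_span = 3L, edge_prob = 0.6,
                                 seed = 1L) {
  stopifnot(n >= 1, n_bags >= 1)
  with_seed(seed, {
    a <- sample.int(n_bags, n, replace = TRUE)
    b <- pmin(a + sample.int(max_span, n, replace = TRUE) - 1L, n_bags)
    bags <- lapply(seq_len(n_bags), function(i)
      as.character(which(a <= i & i <= b)))
    links <- if (n_bags > 1) cbind(seq_len(n_bags - 1), 2:n_bags) else NULL
    td <- tree_decomposition(stats::setNames(bags, seq_len(n_bags)), links)
    co <- unique(do.call(rbind, lapply(bags, function(bg) {
      if (length(bg) < 2) return(NULL)
      t(utils::combn(sort(as.integer(bg)), 2))
    })))
    edges <- NULL
    if (!is.null(co) && nrow(co) > 0) {
      keep <- stats::runif(nrow(co)) < edge_prob
      if (any(keep))
        edges <- data.frame(u = as.character(co[keep, 1]),
                            v = as.character(co[keep, 2]))
    }
    list(graph = diet_graph(as.character(seq_len(n)), edges), td = td)
  })
}

#' Trivial single-bag decomposition
#'
#' One bag containing every vertex (width n - 1); the decomposition used to
#' reduce clique finding to the diet problem on a fixed-width target.
#'
#' @param g a [diet_graph()].
#' @return A [tree_decomposition()] with one bag.
#' @export
single_bag_decomposition <- function(g) {
  tree_decomposition(list("1" = g$vertices))
}

#' Path of identical full bags
#'
#' `length` bags (default n - 1), each containing all vertices, linked in a
#' path: the decomposition for which a diet to width 1 keeps n - 1 edges
#' exactly when the graph has a spanning caterpillar.
#'
#' @param g a [diet_graph()].
#' @param length number of bags; defaults to `max(n - 1, 1)`.
#' @return A [tree_decomposition()].
#' @export
full_bag_path_decomposition <- function(g, length = NULL) {
  n <- base::length(g$vertices)
  if (is.null(length)) length <- max(n - 1L, 1L)
  stopifnot(length >= 1)
  bags <- rep(list(g$vertices), length)
  links <- if (length > 1) cbind(seq_len(length - 1L), 2:length) else NULL
  tree_decomposition(stats::setNames(bags, seq_len(length)), links)
}

#' Is the graph a caterpillar forest?
#'
#' True iff the graph is acyclic and, in every connected component, removing
#' all degree-1 vertices leaves a (possibly empty) simple path — i.e. every
#' component is a caterpillar, the trees of pathwidth at most 1.
#'
#' @param g a [diet_graph()].
#' @return Logical.
#' @export
is_caterpillar_forest <- function(g) {
  n <- length(g$vertices)
  if (n == 0) return(TRUE)
  adj <- graph_adjacency(g)
  comp <- rep(NA_integer_, n); nc <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    nc <- nc + 1L
    frontier <- s; comp[s] <- nc
    while (length(frontier) > 0) {
      nxt <- setdiff(unlist(adj[frontier]), which(!is.na(comp)))
      comp[nxt] <- nc; frontier <- nxt
    }
  }
  if (nrow(g$edges) != n - nc) return(FALSE)     # a cycle exists
  deg <- vapply(adj, length, integer(1))
  spine <- which(deg >= 2)
  # degree within the spine must be <= 2 for a caterpillar
  all(vapply(spine, function(v) sum(adj[[v]] %in% spine) <= 2, logical(1)))
}

#' Seeded regular multipartite graph (circulant-style bicliques)
#'
#' Builds a k-partite graph with equal part sizes n in which every vertex
#' has the same degree delta = t * (k - 1): between each pair of parts, t
#' distinct cyclic-shift perfect matchings are inserted (shift 0 joins
#' position a to position a, shift s joins a to a + s mod n). Shifts are
#' sampled with the seed; shift 0 can be forced for every pair, which plants
#' a k-clique at position 1.
#'
#' @param k number of parts (>= 2).
#' @param n part size (>= 1).
#' @param t matchings per part pair (1 <= t <= n).
#' @param seed integer seed.
#' @param force_zero_shift if `TRUE`, shift 0 is among the t shifts for every
#'   pair, so vertices `p1_1, ..., pk_1` form a k-clique.
#' @return A list: `graph` (a [diet_graph()]), `parts` (list of label
#'   vectors), `delta` (the common degree).
#' @export
random_regular_multipartite <- function(k, n, t = 1L, seed = 1L,
                                        force_zero_shift = TRUE) {
  stopifnot(k >= 2, n >= 1, t >= 1, t <= n)
  parts <- lapply(seq_len(k), function(i) paste0("p", i, "_", seq_len(n)))
  eu <- ev <- character(0)
  with_seed(seed, {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        pool <- 0:(n - 1)
        shifts <- if (force_zero_shift)
          c(0L, if (t > 1) sample(pool[-1], t - 1L)) else sample(pool, t)
        for (s in shifts) {
          for (a in seq_len(n)) {
            b <- ((a - 1L + s) %% n) + 1L
            eu <- c(eu, parts[[i]][a]); ev <- c(ev, parts[[j]][b])
          }
        }
      }
    }
  })
  g <- diet_graph(unlist(parts),
                  if (length(eu) > 0) data.frame(u = eu, v = ev) else NULL)
  list(graph = g, parts = parts, delta = as.integer(t * (k - 1)))
}

#' Clique-detection gadget instance
#'
#' From a delta-regular k-partite graph with equal part sizes n, builds the
#' enlarged graph and 2k+1-bag tree decomposition for which a 1-diet loses
#' at most L = delta*k - choose(k,2) edges exactly when the input graph has
#' a k-clique: k fresh cliques K_i of size N+1, k fresh sets Z_i of N
#' vertices fully joined to part V_i, with N = max(|V|, L+1), and bags
#' T0 = V, T1i = V_i + K_i, T2i = V_i + Z_i linked T2i - T1i - T0.
#'
#' @param g a [diet_graph()], k-partite and delta-regular.
#' @param parts list of k character vectors partitioning the vertices of `g`,
#'   all the same size.
#' @return A list: `graph`, `td`, `L`, `N`, `delta`, `k`.
#' @export
clique_reduction_gadget <- function(g, parts) {
  stopifnot(inherits(g, "diet_graph"))
  k <- length(parts)
  stopifnot(k >= 2)
  sizes <- vapply(parts, length, integer(1))
  if (length(unique(sizes)) != 1) stop("parts must have equal sizes")
  if (!setequal(unlist(parts), g$vertices))
    stop("parts must partition the graph's vertices")
  part_of <- stats::setNames(rep(seq_len(k), sizes), unlist(parts))
  if (any(part_of[g$edges$u] == part_of[g$edges$v]))
    stop("graph is not k-partite for the given parts")
  deg <- with(graph_summary(g), c(degree_min, degree_max))
  if (deg[1] != deg[2]) stop("graph must be regular")
  delta <- deg[1]
  L <- delta * k - choose(k, 2)
  N <- max(length(g$vertices), L + 1)
  Ki <- lapply(seq_len(k), function(i) paste0("K", i, "_", seq_len(N + 1)))
  Zi <- lapply(seq_len(k), function(i) paste0("Z", i, "_", seq_len(N)))
  eu <- g$edges$u; ev <- g$edges$v
  for (i in seq_len(k)) {
    cl <- utils::combn(Ki[[i]], 2)
    eu <- c(eu, cl[1, ]); ev <- c(ev, cl[2, ])
    bip <- expand.grid(parts[[i]], Zi[[i]], stringsAsFactors = FALSE)
    eu <- c(eu, bip[[1]]); ev <- c(ev, bip[[2]])
  }
  gg <- diet_graph(c(g$vertices, unlist(Ki), unlist(Zi)),
                   data.frame(u = eu, v = ev))
  bags <- list("1" = g$vertices)
  links <- NULL
  for (i in seq_len(k)) {
    bags[[as.character(2 * i)]] <- c(parts[[i]], Ki[[i]])
    bags[[as.character(2 * i + 1)]] <- c(parts[[i]], Zi[[i]])
    links <- rbind(links, c(1L, 2L * i), c(2L * i, 2L * i + 1L))
  }
  list(graph = gg, td = tree_decomposition(bags, links),
       L = as.integer(L), N = as.integer(N),
       delta = as.integer(delta), k = as.integer(k))
}

#' Random pseudoknotted RNA structure graph
#'
#' Backbone path 1..L (backbone-flagged edges) plus `n_helices` helices of
#' `helix_len` stacked base pairs placed on disjoint position blocks.
#' Consecutive helices are paired block-to-block; with probability
#' `crossing_prob` a pair of adjacent helices swaps partners to create a
#' crossing (a pseudoknot). With `crossing_prob = 0` the structure is
#' crossing-free, hence outerplanar with treewidth at most 2.
#'
#' @param L sequence length.
#' @param n_helices number of helices.
#' @param helix_len base pairs per helix.
#' @param crossing_prob per-adjacent-pair probability of a crossing swap.
#' @param seed integer seed.
#' @return A [diet_graph()] with backbone-flagged path edges.
#' @export
random_pseudoknot_graph <- function(L, n_helices, helix_len = 2L,
                                    crossing_prob = 0.3, seed = 1L) {
  stopifnot(L >= 1, n_helices >= 0, helix_len >= 1)
  nb <- 2L * n_helices
  if (nb * helix_len > L) stop("infeasible packing: helices do not fit in L")
  if (n_helices == 0) return(rna_graph(L, integer(0), integer(0)))
  with_seed(seed, {
    slack <- L - nb * helix_len
    cuts <- sort(sample.int(slack + nb, nb))   # stars-and-bars gap sampling
    gaps <- diff(c(0L, cuts)) - 1L
    starts <- integer(nb)
    pos <- 0L
    for (i in seq_len(nb)) {
      pos <- pos + gaps[i]
      starts[i] <- pos + 1L
      pos <- pos + helix_len
    }
    # pair consecutive blocks; adjacent helix pairs may swap to cross
    left <- seq(1L, nb, by = 2L)
    right <- seq(2L, nb, by = 2L)
    if (n_helices >= 2) {
      for (h in seq_len(n_helices - 1)) {
        if (stats::runif(1) < crossing_prob) {
          tmp <- right[h]; right[h] <- left[h + 1]; left[h + 1] <- tmp
          # keep each helix's left block before its right block
          if (left[h] > right[h]) { t2 <- left[h]; left[h] <- right[h]; right[h] <- t2 }
          if (left[h + 1] > right[h + 1]) {
            t2 <- left[h + 1]; left[h + 1] <- right[h + 1]; right[h + 1] <- t2
          }
        }
      }
    }
    pu <- pv <- integer(0)
    for (h in seq_len(n_helices)) {
      a <- starts[left[h]]; bend <- starts[right[h]] + helix_len - 1L
      for (s in 0:(helix_len - 1L)) {
        pu <- c(pu, a + s); pv <- c(pv, bend - s)
      }
    }
    rna_graph(L, pu, pv)
  })
}
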