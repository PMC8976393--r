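#' Brute-force reference solver for the tree-diet problem
#'
#' Exhaustively searches, per vertex, over every connected subset of the bags
#' containing it (its retained occurrences, possibly empty), subject to every
#' bag keeping at most `target_width + 1` vertices, and maximizes the total
#' weight of visible edges (edges whose endpoints share a retained bag).
#' This enumerates exactly the feasible diets — per-bag subset choices whose
#' per-vertex retained bags form connected subtrees — and is entirely
#' independent of the coloring dynamic program, so it serves as ground truth
#' in tests. A guard on the total occurrence count keeps it to small
#' instances.
#'
#' @param g a [diet_graph()].
#' @param td a [tree_decomposition()] (rooted or not) of `g`.
#' @param target_width integer target width.
#' @param weights optional numeric vector of edge weights aligned with
#'   `g$edges`; default all 1 (edge counting).
#' @param max_occurrences guard on the total number of vertex occurrences.
#' @return A list: `objective` (max visible weight), `retained` (named list
#'   vertex -> integer ids of retaining bags), `coloring` (a valid witness
#'   coloring of `root_with_empty_bag(td)` realizing the objective).
#' @export
brute_force_tree_diet <- function(g, td, target_width, weights = NULL,
                                  max_occurrences = 26L) {
  stopifnot(inherits(g, "diet_graph"), inherits(td, "tree_decomposition"))
  if (is.null(weights)) weights <- rep(1, nrow(g$edges))
  stopifnot(length(weights) == nrow(g$edges))
  ids <- bag_ids(td)
  bag_list <- lapply(td$bags, function(b) match(b, g$vertices))
  pos_of_id <- stats::setNames(seq_along(ids), ids)
  links <- td$links
  lm <- if (NROW(links) > 0)
    cbind(pos_of_id[as.character(links[, 1])],
          pos_of_id[as.character(links[, 2])])
  else matrix(integer(), ncol = 2)
  storage.mode(lm) <- "integer"
  em <- cbind(match(g$edges$u, g$vertices), match(g$edges$v, g$vertices))
  storage.mode(em) <- "integer"
  res <- bf_diet_cpp(unname(bag_list), lm, em, as.numeric(weights),
                     length(g$vertices), as.integer(target_width) + 1L,
                     as.integer(max_occurrences))
  retained <- stats::setNames(
    lapply(res$retained, function(p) ids[p]), g$vertices)
  rtd <- root_with_empty_bag(td)
  coloring <- witness_coloring(rtd, retained)
  list(objective = res$objective, retained = retained, coloring = coloring)
}

# build a valid coloring from retained-bag sets: green where retained,
# orange on the path from the top occurrence down to the green subtree (or
# down a deterministic chain if nothing is retained), red elsewhere
witness_coloring <- function(rtd, retained) {
  keys <- names(rtd$bags)
  depth <- bag_depths(rtd)
  coloring <- lapply(rtd$bags, function(b)
    stats::setNames(rep("r", length(b)), b))
  for (v in names(retained)) {
    occ <- bag_ids(rtd)[vapply(rtd$bags, function(b) v %in% b, logical(1))]
    if (length(occ) == 0) next
    top <- occ[which.min(depth[as.character(occ)])]
    greens <- retained[[v]]
    if (length(greens) > 0) {
      for (b in greens) coloring[[as.character(b)]][v] <- "g"
      gtop <- greens[which.min(depth[as.character(greens)])]
      b <- gtop
      while (b != top) {
        b <- rtd$parent[[as.character(b)]]
        coloring[[as.character(b)]][v] <- "o"
      }
    } else {
      b <- top
      repeat {
        coloring[[as.character(b)]][v] <- "o"
        kids <- rtd$children[[as.character(b)]]
        holders <- kids[vapply(kids, function(k)
          v %in% rtd$bags[[as.character(k)]], logical(1))]
        if (length(holders) == 0) break
        b <- min(holders)
      }
    }
  }
  coloring
}

bag_depths <- function(rtd) {
  depth <- stats::setNames(rep(NA_integer_, length(rtd$bags)),
                           names(rtd$bags))
  depth[as.character(rtd$root)] <- 0L
  frontier <- rtd$root
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (b in frontier) {
      for (k in rtd$children[[as.character(b)]]) {
        depth[as.character(k)] <- depth[[as.character(b)]] + 1L
        nxt <- c(nxt, k)
      }
    }
    frontier <- nxt
  }
  depth
}

#' Exact treewidth of a small graph
#'
#' Minimum over all elimination orderings of the largest bag size minus one,
#' computed with the standard subset dynamic program (the fill-in graph after
#' eliminating a set does not depend on the elimination order within the
#' set). Exact, limited to n <= 8 vertices.
#'
#' @param g a [diet_graph()].
#' @return Integer treewidth (-1 for the empty graph).
#' @export
exhaustive_treewidth <- function(g) {
  stopifnot(inherits(g, "diet_graph"))
  n <- length(g$vertices)
  if (n == 0) return(-1L)
  if (n > 8) stop("exhaustive_treewidth is limited to n <= 8")
  adj <- integer(n)
  if (nrow(g$edges) > 0) {
    iu <- match(g$edges$u, g$vertices)
    iv <- match(g$edges$v, g$vertices)
    for (k in seq_along(iu)) {
      adj[iu[k]] <- bitwOr(adj[iu[k]], bitwShiftL(1L, iv[k] - 1L))
      adj[iv[k]] <- bitwOr(adj[iv[k]], bitwShiftL(1L, iu[k] - 1L))
    }
  }
  full <- bitwShiftL(1L, n) - 1L
  # degree of v in the fill graph after eliminating set S: vertices outside
  # S reachable from v through S
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  popcount <- function(x) sum(bitwAnd(x, bits) != 0L)
  deg_after <- function(v, S) {
    vbit <- bits[v]
    seen <- vbit
    frontier <- vbit
    reached <- 0L
    while (frontier != 0L) {
      nxt <- 0L
      for (u in which(bitwAnd(frontier, bits) != 0L))
        nxt <- bitwOr(nxt, adj[u])
      nxt <- bitwAnd(nxt, bitwNot(seen))
      seen <- bitwOr(seen, nxt)
      reached <- bitwOr(reached, bitwAnd(nxt, bitwNot(S)))
      frontier <- bitwAnd(nxt, S)    # only continue expanding through S
    }
    popcount(reached)
  }
  f <- rep(NA_integer_, 2L^n)
  pop <- vapply(0:(2L^n - 1L), popcount, integer(1))
  f[full + 1L] <- -1L
  for (size in (n - 1L):0L) {
    for (S in which(pop == size) - 1L) {
      best <- .Machine$integer.max
      for (v in seq_len(n)) {
        vbit <- bitwShiftL(1L, v - 1L)
        if (bitwAnd(S, vbit) != 0L) next
        cand <- max(deg_after(v, S), f[bitwOr(S, vbit) + 1L])
        if (cand < best) best <- cand
      }
      f[S + 1L] <- best
    }
  }
  as.integer(f[1L])
}
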