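#' @name coloring
#' @title Colorings of vertex occurrences
#' @description
#' The dynamic program assigns one of three colors to every occurrence of a
#' vertex in a rooted decomposition: green (`"g"`, the vertex is kept in the
#' bag), orange (`"o"`, removed here but possibly kept further down), and red
#' (`"r"`, removed from the bag and its whole subtree). A coloring is *valid*
#' when it follows four local rules along each parent-to-child link:
#' \itemize{
#'   \item R1: a vertex of a bag not present in its parent is green or orange;
#'   \item R2: a green vertex is green or red in its children;
#'   \item R3: a red vertex stays red in its children;
#'   \item R4: an orange vertex is orange or green in exactly one child
#'     (unless no child contains it), and red in all other children.
#' }
#' Under these rules the green occurrences of any vertex form a connected
#' subtree, so deleting all non-green occurrences yields a valid (thinner)
#' decomposition of the subgraph of *realizable* edges — edges whose two
#' endpoints are green together in some bag.
#'
#' A full coloring is a named list, one element per bag id, each a named
#' character vector mapping the bag's vertices to `"g"`, `"o"` or `"r"`.
NULL

COLORS <- c("g", "o", "r")

#' Check a coloring against the local validity rules
#'
#' @param rtd a `rooted_decomposition`.
#' @param coloring a full coloring (named list of named character vectors,
#'   one per bag, domains equal to the bags).
#' @return A `validation_report` whose `messages` name the violated rule,
#'   bag and vertex for every violation; `ok` iff there are none.
#' @export
check_coloring_validity <- function(rtd, coloring) {
  stopifnot(inherits(rtd, "rooted_decomposition"))
  msgs <- character(0)
  for (b in bag_ids(rtd)) {
    key <- as.character(b)
    bag <- rtd$bags[[key]]
    f <- coloring[[key]]
    if (is.null(f) || !setequal(names(f), bag) || length(f) != length(bag)) {
      msgs <- c(msgs, paste0("bag ", b,
                             ": coloring domain does not equal the bag"))
      next
    }
    if (!all(f %in% COLORS)) {
      msgs <- c(msgs, paste0("bag ", b, ": invalid color value"))
      next
    }
    p <- rtd$parent[[key]]
    pbag <- if (is.na(p)) character() else rtd$bags[[as.character(p)]]
    pf <- if (is.na(p)) NULL else coloring[[as.character(p)]]
    kids <- rtd$children[[key]]
    for (v in bag) {
      if (!(v %in% pbag)) {
        if (f[[v]] == "r")
          msgs <- c(msgs, paste0("R1: vertex ", v, " introduced red in bag ", b))
      } else if (!is.null(pf)) {
        pc <- pf[[v]]
        if (pc == "g" && !(f[[v]] %in% c("g", "r")))
          msgs <- c(msgs, paste0("R2: vertex ", v, " green in bag ", p,
                                 " but ", f[[v]], " in child ", b))
        if (pc == "r" && f[[v]] != "r")
          msgs <- c(msgs, paste0("R3: vertex ", v, " red in bag ", p,
                                 " but ", f[[v]], " in child ", b))
      }
      if (f[[v]] == "o") {
        holders <- kids[vapply(kids, function(k)
          v %in% rtd$bags[[as.character(k)]], logical(1))]
        if (length(holders) > 0) {
          live <- sum(vapply(holders, function(k)
            coloring[[as.character(k)]][[v]] %in% c("o", "g"), logical(1)))
          if (live != 1)
            msgs <- c(msgs, paste0("R4: orange vertex ", v, " in bag ", b,
                                   " is orange/green in ", live,
                                   " children (expected exactly 1)"))
        }
      }
    }
  }
  structure(list(ok = length(msgs) == 0,
                 uncovered_vertices = character(0),
                 lost_edges = data.frame(),
                 disconnected_vertices = character(0),
                 messages = msgs),
            class = "validation_report")
}

#' Edges realizable under a coloring
#'
#' An edge is realizable when some bag colors both of its endpoints green.
#'
#' @param g a [diet_graph()].
#' @param rtd a `rooted_decomposition` of `g`.
#' @param coloring a valid full coloring.
#' @return The realizable rows of `g$edges`.
#' @export
realizable_edges <- function(g, rtd, coloring) {
  rep_ok <- check_coloring_validity(rtd, coloring)
  if (!rep_ok$ok)
    stop("invalid coloring: ", paste(rep_ok$messages, collapse = "; "))
  e <- g$edges
  if (nrow(e) == 0) return(e)
  real <- logical(nrow(e))
  for (key in names(coloring)) {
    f <- coloring[[key]]
    greens <- names(f)[f == "g"]
    real <- real | (e$u %in% greens & e$v %in% greens)
  }
  e[real, , drop = FALSE]
}

#' Edges newly counted at a parent-to-child link
#'
#' The count set of a link is the set of edges whose endpoints are both green
#' in the child bag, but not both present-and-green in the parent bag. Every
#' realizable edge belongs to the count set of exactly one link of the
#' decomposition (the one entering the root of its green subtree), which is
#' how the dynamic program avoids double counting.
#'
#' @param g a [diet_graph()].
#' @param parent_bag,child_bag character vectors of vertex labels.
#' @param f,fj named color vectors for the two bags.
#' @return The counted rows of `g$edges`.
#' @export
count_set <- function(g, parent_bag, f, child_bag, fj) {
  e <- g$edges
  if (nrow(e) == 0) return(e)
  gc <- names(fj)[fj == "g"]
  gp <- names(f)[f == "g"]
  in_child <- e$u %in% gc & e$v %in% gc
  in_parent <- e$u %in% parent_bag & e$v %in% parent_bag &
    e$u %in% gp & e$v %in% gp
  e[in_child & !in_parent, , drop = FALSE]
}

#' Enumerate assignments of orange vertices to children
#'
#' For each orange vertex of a parent coloring, rule R4 requires picking the
#' one child that may keep it orange or green; vertices contained in no child
#' are omitted from the map. The enumeration is the Cartesian product over
#' orange vertices of the children containing them, in deterministic order.
#'
#' @param f named color vector of the parent bag.
#' @param child_bags list of character vectors (the children's bags), in
#'   child order.
#' @return A list of named integer vectors (vertex -> child index); a single
#'   empty assignment when there is nothing to assign.
#' @export
enumerate_orange_assignments <- function(f, child_bags) {
  oranges <- sort(names(f)[f == "o"])
  holders <- lapply(oranges, function(v)
    which(vapply(child_bags, function(b) v %in% b, logical(1))))
  keep <- vapply(holders, length, integer(1)) > 0
  oranges <- oranges[keep]; holders <- holders[keep]
  if (length(oranges) == 0)
    return(list(stats::setNames(integer(0), character(0))))
  grid <- expand.grid(rev(holders), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(holders)), drop = FALSE]
  lapply(seq_len(nrow(grid)), function(r)
    stats::setNames(as.integer(grid[r, ]), oranges))
}

#' Enumerate child colorings compatible with a parent coloring
#'
#' Applies the per-vertex cases of the recurrence: a vertex absent from the
#' parent may be orange or green; a green parent vertex may stay green or
#' turn red; an orange parent vertex assigned to this child may be orange or
#' green, and must be red if assigned elsewhere; a red parent vertex stays
#' red.
#'
#' @param child_bag character vector of the child's vertices.
#' @param parent_bag character vector of the parent's vertices.
#' @param f named color vector of the parent bag.
#' @param m an assignment from [enumerate_orange_assignments()].
#' @param child_index index of this child in the parent's child order.
#' @return A list of named color vectors for the child bag, in canonical
#'   order (vertices sorted, colors ordered g < o < r).
#' @export
enumerate_compatible <- function(child_bag, parent_bag, f, m, child_index) {
  verts <- sort(child_bag)
  options <- lapply(verts, function(u) {
    if (!(u %in% parent_bag)) return(c("g", "o"))
    switch(f[[u]],
           g = c("g", "r"),
           r = "r",
           o = if (!is.null(m[[u]]) && !is.na(m[u]) && m[[u]] == child_index)
             c("g", "o") else "r")
  })
  if (length(verts) == 0)
    return(list(stats::setNames(character(0), character(0))))
  grid <- expand.grid(rev(options), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(options)), drop = FALSE]
  lapply(seq_len(nrow(grid)), function(r)
    stats::setNames(as.character(unlist(grid[r, ])), verts))
}
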