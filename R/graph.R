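#' Construct a graph with weighted, backbone-flagged edges
#'
#' The basic container used throughout the package: an ordered set of opaque
#' vertex labels plus a set of undirected edges. Each edge carries a
#' non-negative weight (default 1) and a logical backbone flag (default
#' `FALSE`) marking, for RNA structure graphs, the covalent chain between
#' consecutive nucleotides as opposed to a base pair.
#'
#' Edges are stored with their endpoints in vertex order (the position of the
#' label in `vertices`), so an unordered pair is a unique key: self-loops and
#' duplicate edges are rejected.
#'
#' @param vertices character vector of distinct vertex labels (coerced).
#' @param edges `NULL`, or a data frame / matrix with columns `u`, `v` and
#'   optionally `weight` and `backbone`.
#' @return An object of class `diet_graph` with elements `vertices` and
#'   `edges` (a data frame with columns `u`, `v`, `weight`, `backbone`).
#' @examples
#' g <- diet_graph(c("1", "2", "3"),
#'                 data.frame(u = c("1", "2"), v = c("2", "3")))
#' graph_summary(g)
#' @export
diet_graph <- function(vertices = character(), edges = NULL) {
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices))
    stop("duplicate vertex labels: ",
         paste(unique(vertices[duplicated(vertices)]), collapse = ", "))
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(u = character(), v = character(),
                        weight = numeric(), backbone = logical(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("u", "v") %in% names(edges)))
      stop("edges must have columns 'u' and 'v'")
    edges$u <- as.character(edges$u)
    edges$v <- as.character(edges$v)
    if (is.null(edges$weight)) edges$weight <- 1
    edges$weight <- as.numeric(edges$weight)
    if (is.null(edges$backbone)) edges$backbone <- FALSE
    edges$backbone <- as.logical(edges$backbone)
    edges <- edges[c("u", "v", "weight", "backbone")]
  }
  g <- structure(list(vertices = vertices, edges = edges),
                 class = "diet_graph")
  validate_diet_graph(g)
}

validate_diet_graph <- function(g) {
  e <- g$edges
  iu <- match(e$u, g$vertices)
  iv <- match(e$v, g$vertices)
  if (anyNA(iu) || anyNA(iv)) {
    bad <- unique(c(e$u[is.na(iu)], e$v[is.na(iv)]))
    stop("edge endpoint(s) not declared as vertices: ",
         paste(bad, collapse = ", "))
  }
  if (any(iu == iv))
    stop("self-loops are not allowed (vertex ",
         paste(unique(e$u[iu == iv]), collapse = ", "), ")")
  if (any(e$weight < 0)) stop("edge weights must be >= 0")
  # normalize endpoint order so the unordered pair is the key
  swap <- iu > iv
  if (any(swap)) {
    tmp <- e$u[swap]; e$u[swap] <- e$v[swap]; e$v[swap] <- tmp
  }
  key <- paste(e$u, e$v, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate edges: ",
         paste(unique(gsub("\r", "-", key[duplicated(key)])), collapse = ", "))
  ord <- order(match(e$u, g$vertices), match(e$v, g$vertices))
  g$edges <- e[ord, , drop = FALSE]
  rownames(g$edges) <- NULL
  g
}

# canonical "u|v" keys, endpoints already normalized
edge_keys <- function(edges) {
  if (NROW(edges) == 0) return(character())
  paste(edges$u, edges$v, sep = "|")
}

#' @export
print.diet_graph <- function(x, ...) {
  s <- graph_summary(x)
  cat(sprintf("<diet_graph> %d vertices, %d edges (%d backbone)\n",
              s$n, s$m, s$m_backbone))
  invisible(x)
}

#' Summarize a graph
#'
#' @param g a [diet_graph()].
#' @return A list with `n` (vertices), `m` (edges), `m_backbone`
#'   (backbone-flagged edges), `degree_min`, `degree_max`.
#' @export
graph_summary <- function(g) {
  stopifnot(inherits(g, "diet_graph"))
  n <- length(g$vertices)
  m <- nrow(g$edges)
  deg <- integer(n)
  if (m > 0) {
    tab <- table(factor(c(g$edges$u, g$edges$v), levels = g$vertices))
    deg <- as.integer(tab)
  }
  list(n = n, m = m,
       m_backbone = sum(g$edges$backbone),
       degree_min = if (n == 0) 0L else min(deg),
       degree_max = if (n == 0) 0L else max(deg))
}

# adjacency list as list of integer vectors (indices into vertices)
graph_adjacency <- function(g) {
  n <- length(g$vertices)
  adj <- rep(list(integer()), n)
  if (nrow(g$edges) > 0) {
    iu <- match(g$edges$u, g$vertices)
    iv <- match(g$edges$v, g$vertices)
    for (k in seq_along(iu)) {
      adj[[iu[k]]] <- c(adj[[iu[k]]], iv[k])
      adj[[iv[k]]] <- c(adj[[iv[k]]], iu[k])
    }
  }
  adj
}

# induced edge count on a set of vertex indices
induced_edge_count <- function(g, idx) {
  if (nrow(g$edges) == 0) return(0L)
  iu <- match(g$edges$u, g$vertices)
  iv <- match(g$edges$v, g$vertices)
  sum(iu %in% idx & iv %in% idx)
}
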