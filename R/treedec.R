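#' Construct a tree decomposition
#'
#' A tree decomposition is a tree whose nodes ("bags") are vertex subsets of
#' a graph. Its width is the size of its largest bag minus one (-1 when there
#' are no bags). This constructor checks only the tree structure; whether the
#' decomposition is valid *for a particular graph* is the job of
#' [validate_decomposition()].
#'
#' @param bags a list of character vectors (vertex labels), named by positive
#'   integer bag ids; unnamed lists get ids `1..k`.
#' @param links a 2-column matrix (or data frame) of bag-id pairs forming the
#'   tree; may be empty for 0 or 1 bags.
#' @return An object of class `tree_decomposition`.
#' @export
tree_decomposition <- function(bags = list(), links = NULL) {
  if (length(bags) > 0 && is.null(names(bags)))
    names(bags) <- as.character(seq_along(bags))
  ids <- as.integer(names(bags))
  if (anyNA(ids) || any(ids <= 0)) stop("bag ids must be positive integers")
  if (anyDuplicated(ids)) stop("repeated bag id")
  bags <- lapply(bags, as.character)
  if (is.null(links) || NROW(links) == 0) {
    links <- matrix(integer(), ncol = 2)
  } else {
    links <- as.matrix(links)
    storage.mode(links) <- "integer"
    if (ncol(links) != 2) stop("links must have two columns")
  }
  if (NROW(links) > 0 && !all(links %in% ids))
    stop("link endpoint refers to an undeclared bag id")
  td <- structure(list(bags = bags, links = links),
                  class = "tree_decomposition")
  if (length(bags) > 0 && !is_tree_links(ids, links))
    stop("links do not form a single tree over all bag ids")
  td
}

is_tree_links <- function(ids, links) {
  k <- length(ids)
  if (NROW(links) != k - 1) return(FALSE)
  if (k <= 1) return(TRUE)
  # connectivity by BFS over bag adjacency
  adj <- bag_adjacency(ids, links)
  seen <- ids[1]; frontier <- ids[1]
  while (length(frontier) > 0) {
    nxt <- setdiff(unlist(adj[as.character(frontier)], use.names = FALSE), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  length(seen) == k
}

bag_adjacency <- function(ids, links) {
  adj <- stats::setNames(rep(list(integer()), length(ids)), as.character(ids))
  if (NROW(links) > 0) {
    for (r in seq_len(nrow(links))) {
      a <- links[r, 1]; b <- links[r, 2]
      adj[[as.character(a)]] <- c(adj[[as.character(a)]], b)
      adj[[as.character(b)]] <- c(adj[[as.character(b)]], a)
    }
  }
  adj
}

bag_ids <- function(td) as.integer(names(td$bags))

#' Width of a tree decomposition
#'
#' The size of its largest bag minus 1; -1 for a decomposition with no bags
#' (or a single empty bag).
#' @param td a [tree_decomposition()].
#' @return Integer width.
#' @export
decomposition_width <- function(td) {
  if (length(td$bags) == 0) return(-1L)
  as.integer(max(vapply(td$bags, length, integer(1))) - 1L)
}

#' @export
print.tree_decomposition <- function(x, ...) {
  cat(sprintf("<%s> %d bags, width %d\n",
              class(x)[1], length(x$bags), decomposition_width(x)))
  invisible(x)
}

#' Parse a PACE-style .td tree decomposition file
#'
#' Format: header `s td <numBags> <maxBagSize> <n>`, bag lines
#' `b <id> <v...>`, then tree-edge lines `<i> <j>`; comment lines start `c`.
#'
#' @param text file content as a string or character vector of lines.
#' @return A [tree_decomposition()] with vertex labels the decimal ids.
#' @export
parse_td <- function(text) {
  lines <- split_lines(text)
  keep <- !grepl("^\\s*$", lines) & !grepl("^c($|\\s)", lines)
  lns <- which(keep)
  if (length(lns) == 0) stop("empty .td input: no header line")
  header <- lines[lns[1]]
  hm <- regmatches(header,
                   regexec("^s\\s+td\\s+(\\d+)\\s+(\\d+)\\s+(\\d+)\\s*$",
                           header))[[1]]
  if (length(hm) != 4)
    stop("line ", lns[1], ": malformed header '", header,
         "' (expected 's td <numBags> <maxBagSize> <n>')")
  nbags <- as.integer(hm[2])
  bags <- list(); lu <- lv <- integer(0)
  for (i in lns[-1]) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (f[1] == "b") {
      if (length(f) < 2) stop("line ", i, ": malformed bag line")
      id <- suppressWarnings(as.integer(f[2]))
      if (is.na(id)) stop("line ", i, ": non-integer bag id")
      if (!is.null(bags[[as.character(id)]]))
        stop("line ", i, ": repeated bag id ", id)
      bags[[as.character(id)]] <- if (length(f) > 2) f[-(1:2)] else character()
    } else {
      if (length(f) != 2) stop("line ", i, ": malformed tree-edge line")
      ab <- suppressWarnings(as.integer(f))
      if (anyNA(ab)) stop("line ", i, ": non-integer bag id in tree edge")
      lu <- c(lu, ab[1]); lv <- c(lv, ab[2])
    }
  }
  if (length(bags) != nbags)
    stop("header declares ", nbags, " bags but ", length(bags), " were given")
  tree_decomposition(bags, cbind(lu, lv))
}

#' Write a tree decomposition in PACE-style .td format
#'
#' @param td a [tree_decomposition()].
#' @param n number of graph vertices for the header; defaults to the largest
#'   integer vertex label occurring in the bags (0 if none).
#' @return A single string; `parse_td(write_td(td))` reproduces the content.
#' @export
write_td <- function(td, n = NULL) {
  stopifnot(inherits(td, "tree_decomposition"))
  ids <- sort(bag_ids(td))
  sizes <- vapply(td$bags, length, integer(1))
  if (is.null(n)) {
    labs <- suppressWarnings(as.integer(unlist(td$bags, use.names = FALSE)))
    n <- if (length(labs) == 0 || all(is.na(labs))) 0L else max(labs, na.rm = TRUE)
  }
  header <- sprintf("s td %d %d %d", length(ids),
                    if (length(ids) == 0) 0L else max(sizes), n)
  blines <- vapply(ids, function(id) {
    b <- td$bags[[as.character(id)]]
    vo <- suppressWarnings(as.integer(b))
    b <- if (!anyNA(vo)) b[order(vo)] else sort(b)
    trimws(paste("b", id, paste(b, collapse = " ")))
  }, character(1))
  elines <- character(0)
  if (NROW(td$links) > 0) {
    a <- pmin(td$links[, 1], td$links[, 2])
    b <- pmax(td$links[, 1], td$links[, 2])
    ord <- order(a, b)
    elines <- sprintf("%d %d", a[ord], b[ord])
  }
  paste(c(header, blines, elines), collapse = "\n")
}

#' Check that a tree decomposition is valid for a graph
#'
#' Diagnoses the three defects that can make a decomposition invalid for a
#' graph: vertices covered by no bag, edges visible in no bag (*lost* edges),
#' and vertices whose bags do not induce a connected subtree. Defects are
#' returned as data, not raised as errors.
#'
#' @param g a [diet_graph()].
#' @param td a [tree_decomposition()].
#' @return A list of class `validation_report`: `ok`, `uncovered_vertices`,
#'   `lost_edges` (data frame), `disconnected_vertices`, `messages`.
#' @export
validate_decomposition <- function(g, td) {
  stopifnot(inherits(g, "diet_graph"), inherits(td, "tree_decomposition"))
  ids <- bag_ids(td)
  occ <- bag_occurrences(td, g$vertices)
  uncovered <- g$vertices[vapply(occ, length, integer(1)) == 0]
  vl <- visible_and_lost_edges(g, td)
  adj <- bag_adjacency(ids, td$links)
  disconnected <- character(0)
  for (v in g$vertices) {
    bs <- occ[[v]]
    if (length(bs) <= 1) next
    seen <- bs[1]; frontier <- bs[1]
    while (length(frontier) > 0) {
      nxt <- setdiff(intersect(
        unlist(adj[as.character(frontier)], use.names = FALSE), bs), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    if (length(seen) < length(bs)) disconnected <- c(disconnected, v)
  }
  msgs <- character(0)
  if (length(uncovered) > 0)
    msgs <- c(msgs, paste0("vertices in no bag: ",
                           paste(uncovered, collapse = ", ")))
  if (nrow(vl$lost) > 0)
    msgs <- c(msgs, paste0("edges visible in no bag: ",
                           paste(edge_keys(vl$lost), collapse = ", ")))
  if (length(disconnected) > 0)
    msgs <- c(msgs, paste0("vertices with disconnected bag sets: ",
                           paste(disconnected, collapse = ", ")))
  structure(list(ok = length(msgs) == 0,
                 uncovered_vertices = uncovered,
                 lost_edges = vl$lost,
                 disconnected_vertices = disconnected,
                 messages = msgs),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) cat("<validation_report> ok\n")
  else cat("<validation_report> INVALID\n ",
           paste(x$messages, collapse = "\n  "), "\n")
  invisible(x)
}

# list vertex -> integer bag ids containing it
bag_occurrences <- function(td, vertices) {
  occ <- stats::setNames(rep(list(integer()), length(vertices)), vertices)
  for (id in bag_ids(td)) {
    for (v in td$bags[[as.character(id)]]) {
      if (!is.null(occ[[v]])) occ[[v]] <- c(occ[[v]], id)
    }
  }
  occ
}

#' Partition edges into visible and lost
#'
#' An edge is visible in a decomposition if some bag contains both endpoints,
#' otherwise it is lost.
#'
#' @param g a [diet_graph()].
#' @param td a [tree_decomposition()].
#' @return A list with data frames `visible` and `lost` (rows of `g$edges`).
#' @export
visible_and_lost_edges <- function(g, td) {
  e <- g$edges
  if (nrow(e) == 0) return(list(visible = e, lost = e))
  vis <- logical(nrow(e))
  for (b in td$bags) {
    inb <- e$u %in% b & e$v %in% b
    vis <- vis | inb
  }
  list(visible = e[vis, , drop = FALSE], lost = e[!vis, , drop = FALSE])
}

#' Is the decomposition a path decomposition?
#'
#' True iff the underlying tree is a single path (every bag has at most two
#' neighbors); single-bag and empty decompositions qualify.
#' @param td a [tree_decomposition()].
#' @return Logical.
#' @export
is_path_decomposition <- function(td) {
  ids <- bag_ids(td)
  if (length(ids) <= 1) return(TRUE)
  deg <- table(factor(c(td$links[, 1], td$links[, 2]), levels = ids))
  all(deg <= 2)
}
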