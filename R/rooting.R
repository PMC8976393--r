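#' Root a tree decomposition at an empty bag
#'
#' The dynamic program assumes the decomposition is rooted at an empty bag.
#' If the decomposition already has an empty bag, the one with the smallest
#' id becomes the root (making the operation idempotent up to isomorphism);
#' otherwise a fresh empty bag (id = max id + 1) is linked to the bag with
#' the smallest id and becomes the root. All original bags and links are
#' preserved, so the width and the visible/lost edge sets are unchanged.
#'
#' @param td a [tree_decomposition()].
#' @return An object of class `rooted_decomposition` (also a
#'   `tree_decomposition`) with elements `root`, `parent` (named integer
#'   vector, `NA` at the root), `children` (named list of integer vectors).
#' @export
root_with_empty_bag <- function(td) {
  stopifnot(inherits(td, "tree_decomposition"))
  bags <- td$bags; links <- td$links
  if (length(bags) == 0) {
    bags <- list("1" = character())
    links <- matrix(integer(), ncol = 2)
    root <- 1L
  } else {
    ids <- bag_ids(td)
    empties <- ids[vapply(td$bags, length, integer(1)) == 0]
    if (length(empties) > 0) {
      root <- min(empties)
    } else {
      root <- max(ids) + 1L
      bags[[as.character(root)]] <- character()
      links <- rbind(links, c(root, min(ids)))
    }
  }
  as_rooted(tree_decomposition(bags, links), root)
}

# orient an (already tree-shaped) decomposition from a chosen root bag
as_rooted <- function(td, root) {
  ids <- bag_ids(td)
  adj <- bag_adjacency(ids, td$links)
  parent <- stats::setNames(rep(NA_integer_, length(ids)), as.character(ids))
  children <- stats::setNames(rep(list(integer()), length(ids)),
                              as.character(ids))
  frontier <- root; seen <- root
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (b in frontier) {
      kids <- sort(setdiff(adj[[as.character(b)]], seen))
      children[[as.character(b)]] <- kids
      for (k in kids) parent[[as.character(k)]] <- b
      nxt <- c(nxt, kids); seen <- c(seen, kids)
    }
    frontier <- nxt
  }
  structure(list(bags = td$bags, links = td$links, root = as.integer(root),
                 parent = parent, children = children),
            class = c("rooted_decomposition", "tree_decomposition"))
}

#' Maximum number of children over the bags of a rooted decomposition
#' @param rtd a [root_with_empty_bag()] result.
#' @return Integer.
#' @export
max_children <- function(rtd) {
  stopifnot(inherits(rtd, "rooted_decomposition"))
  if (length(rtd$children) == 0) return(0L)
  max(vapply(rtd$children, length, integer(1)))
}

#' Make a rooted decomposition binary by chaining bag copies
#'
#' A bag X with children Y1..Yc (c > 2) is replaced by a chain of c-1 copies
#' of X: copy t has children Yt and the next copy, and the last copy has the
#' final two original children. The result is a valid decomposition of the
#' same graph with unchanged width and connected per-vertex bag sets; copies
#' of a bag may later be thinned differently, which can only reduce the
#' number of lost edges.
#'
#' @param rtd a `rooted_decomposition`.
#' @return A `rooted_decomposition` in which every bag has at most 2 children.
#' @export
binarize <- function(rtd) {
  stopifnot(inherits(rtd, "rooted_decomposition"))
  bags <- rtd$bags
  next_id <- if (length(bags) == 0) 1L else max(bag_ids(rtd)) + 1L
  new_bags <- list()
  new_links <- matrix(integer(), ncol = 2)
  recurse <- function(b, parent_new) {
    new_bags[[as.character(b)]] <<- bags[[as.character(b)]]
    if (!is.na(parent_new))
      new_links <<- rbind(new_links, c(parent_new, b))
    kids <- rtd$children[[as.character(b)]]
    if (length(kids) <= 2) {
      for (k in kids) recurse(k, b)
    } else {
      chain <- c(b, integer(length(kids) - 2))
      for (t in 2:(length(kids) - 1)) {
        chain[t] <- next_id
        next_id <<- next_id + 1L
        new_bags[[as.character(chain[t])]] <<- bags[[as.character(b)]]
        new_links <<- rbind(new_links, c(chain[t - 1], chain[t]))
      }
      for (t in seq_len(length(kids) - 1)) recurse(kids[t], chain[t])
      recurse(kids[length(kids)], chain[length(chain)])
    }
  }
  recurse(rtd$root, NA_integer_)
  as_rooted(tree_decomposition(new_bags, new_links), rtd$root)
}
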