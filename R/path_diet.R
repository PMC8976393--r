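#' Enumerate d-simple colorings of one bag
#'
#' A coloring of a path decomposition is d-simple when every bag has at most
#' d orange and at most d red vertices. On path decompositions an optimal
#' d-diet can always be found among d-simple colorings, which shrinks the
#' per-bag state space from 3^|bag| to O(|bag|^(2d)).
#'
#' @param bag character vector of vertex labels.
#' @param d positive integer width reduction.
#' @param target_width the target width; colorings with more than
#'   `target_width + 1` green vertices are excluded.
#' @return A list of named color vectors in canonical order.
#' @export
enumerate_d_simple_colorings <- function(bag, d, target_width) {
  stopifnot(d >= 1)
  vx <- sort(as.character(bag))
  St <- state_matrix(length(vx))
  keep <- d_simple_filter(d, target_width)(St, vx)
  lapply(which(keep), function(r)
    stats::setNames(COLORS[St[r, ] + 1L], vx))
}

d_simple_filter <- function(d, target_width) {
  function(St, vx) {
    if (ncol(St) == 0) return(rep(TRUE, nrow(St)))
    rowSums(St == 1L) <= d & rowSums(St == 2L) <= d &
      rowSums(St == 0L) <= target_width + 1L
  }
}

#' Diet a path decomposition via d-simple colorings
#'
#' Same contract as [tree_diet()] but specialized to path decompositions:
#' the dynamic program only visits d-simple bag colorings (at most d orange
#' and d red per bag), which does not change the optimum. The path is rooted
#' internally at a fresh empty bag appended at one end (the end with the
#' smallest bag id becomes the far end). If some bag would need more than 2d
#' removals to reach the target width the d-simple space is infeasible by
#' construction; the function then falls back to the unrestricted dynamic
#' program and says so via a message.
#'
#' @param g a [diet_graph()].
#' @param pd a [tree_decomposition()] whose tree is a path.
#' @param params a [diet_params()], or an integer target width.
#' @return A `diet_result` (see [tree_diet()]).
#' @export
path_diet <- function(g, pd, params) {
  if (!inherits(params, "diet_params")) params <- diet_params(params)
  stopifnot(inherits(g, "diet_graph"), inherits(pd, "tree_decomposition"))
  if (!is_path_decomposition(pd))
    stop("not a path decomposition; use tree_diet() for general trees")
  rep_in <- validate_decomposition(g, pd)
  if (!rep_in$ok)
    stop("input decomposition is not valid for the graph:\n  ",
         paste(rep_in$messages, collapse = "\n  "))
  rtd <- root_path_at_end(pd)
  width <- decomposition_width(pd)
  d <- width - params$target_width
  if (d <= 0) return(run_diet_dp(g, rtd, params, state_filter = NULL))
  sizes <- vapply(pd$bags, length, integer(1))
  if (any(sizes - 2L * d > params$target_width + 1L)) {
    message("some bag needs more than ", 2L * d,
            " removals; falling back to the unrestricted dynamic program")
    return(run_diet_dp(g, rtd, params, state_filter = NULL))
  }
  run_diet_dp(g, rtd, params,
              state_filter = d_simple_filter(d, params$target_width))
}

# root a path decomposition at a fresh empty bag appended at one end;
# the end with the smallest id becomes the far end
root_path_at_end <- function(pd) {
  ids <- bag_ids(pd)
  if (length(ids) == 0) return(root_with_empty_bag(pd))
  deg <- table(factor(c(pd$links[, 1], pd$links[, 2]), levels = ids))
  ends <- ids[deg <= 1]
  if (length(ends) == 0) ends <- ids          # single bag
  attach_to <- max(ends)                      # min(ends) is the far end
  nid <- max(ids) + 1L
  bags <- pd$bags
  bags[[as.character(nid)]] <- character()
  links <- rbind(pd$links, c(nid, attach_to))
  as_rooted(tree_decomposition(bags, links), nid)
}
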