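#' Parameters for a tree diet
#'
#' @param target_width integer target width `tw'` (>= -1; -1 empties every
#'   bag and loses all edges).
#' @param weight_mode `"count"` treats every edge as weight 1; `"weight"`
#'   maximizes total realizable edge weight.
#' @param backbone_protect if `TRUE`, backbone edges are re-weighted to
#'   (sum of non-backbone weights) + 1 before optimizing, so a diet keeping
#'   the whole backbone is always preferred when one exists. Protection is a
#'   weighting scheme, not a hard constraint: if no backbone-preserving diet
#'   exists, the lost backbone edges are reported and a warning is raised.
#' @return A list of class `diet_params`.
#' @export
diet_params <- function(target_width,
                        weight_mode = c("count", "weight"),
                        backbone_protect = FALSE) {
  target_width <- as.integer(target_width)
  if (is.na(target_width) || target_width < -1L)
    stop("target_width must be an integer >= -1")
  structure(list(target_width = target_width,
                 weight_mode = match.arg(weight_mode),
                 backbone_protect = isTRUE(backbone_protect)),
            class = "diet_params")
}

#' Thin a tree decomposition to a target width, losing minimal edge weight
#'
#' Dynamic program over the rooted decomposition: each bag coloring `f` (one
#' of green/orange/red per vertex) indexes a table cell holding the best
#' total weight of edges realizable strictly below that bag, `-Inf` when `f`
#' has more than `target_width + 1` green vertices. The recurrence maximizes,
#' over assignments of orange vertices to children and over compatible child
#' colorings, the child's cell plus the weight of edges newly counted at the
#' link (see [count_set()]). The optimum is read at the empty root bag, and
#' a traceback reconstructs a globally valid coloring.
#'
#' @param g a [diet_graph()].
#' @param rtd a `rooted_decomposition` of `g` (root bag empty); see
#'   [root_with_empty_bag()]. Any number of children per bag is accepted;
#'   running time grows with the maximum child count, so [binarize()] first
#'   when it exceeds 2.
#' @param params a [diet_params()], or an integer target width.
#' @return A list of class `diet_result`: `objective` (max realizable weight
#'   under the optimized weights), `coloring`, `thinned` (the dieted
#'   decomposition, width <= max(target, 0)), `kept_edges`, `lost_edges`,
#'   `lost_backbone`, `total_weight`, `input_width`, `target_width`,
#'   `weight_mode`, `backbone_protect`, `states_visited`.
#' @export
tree_diet <- function(g, rtd, params) {
  if (!inherits(params, "diet_params")) params <- diet_params(params)
  stopifnot(inherits(g, "diet_graph"), inherits(rtd, "rooted_decomposition"))
  rep_in <- validate_decomposition(g, rtd)
  if (!rep_in$ok)
    stop("input decomposition is not valid for the graph:\n  ",
         paste(rep_in$messages, collapse = "\n  "))
  if (length(rtd$bags[[as.character(rtd$root)]]) != 0)
    stop("root bag must be empty; use root_with_empty_bag()")
  run_diet_dp(g, rtd, params, state_filter = NULL)
}

# shared driver for tree_diet / path_diet
run_diet_dp <- function(g, rtd, params, state_filter) {
  w_eff <- effective_weights(g, params)
  eng <- diet_engine(g, rtd, params$target_width, w_eff, state_filter)
  finish_diet(g, rtd, params, eng)
}

effective_weights <- function(g, params) {
  w <- if (params$weight_mode == "count") rep(1, nrow(g$edges)) else g$edges$weight
  if (params$backbone_protect && any(g$edges$backbone)) {
    boost <- sum(w[!g$edges$backbone]) + 1
    w[g$edges$backbone] <- boost
  }
  w
}

finish_diet <- function(g, rtd, params, eng) {
  kept <- realizable_edges(g, rtd, eng$coloring)
  lost_mask <- !(edge_keys(g$edges) %in% edge_keys(kept))
  lost <- g$edges[lost_mask, , drop = FALSE]
  lost_backbone <- lost[lost$backbone, , drop = FALSE]
  if (params$backbone_protect && nrow(lost_backbone) > 0)
    warning("no backbone-preserving diet at this width: ",
            nrow(lost_backbone), " backbone edge(s) lost", call. = FALSE)
  thinned <- apply_coloring(rtd, eng$coloring, g)
  structure(list(
    objective = eng$objective,
    coloring = eng$coloring,
    thinned = thinned,
    kept_edges = kept,
    lost_edges = lost,
    lost_backbone = lost_backbone,
    total_weight = sum(effective_weights(g, params)),
    input_width = decomposition_width(rtd),
    target_width = params$target_width,
    weight_mode = params$weight_mode,
    backbone_protect = params$backbone_protect,
    states_visited = eng$states_visited
  ), class = "diet_result")
}

#' @export
print.diet_result <- function(x, ...) {
  cat(sprintf(paste0("<diet_result> width %d -> %d: %d/%d edges kept, ",
                     "%d lost (%d backbone)\n"),
              x$input_width, x$target_width, nrow(x$kept_edges),
              nrow(x$kept_edges) + nrow(x$lost_edges),
              nrow(x$lost_edges), nrow(x$lost_backbone)))
  invisible(x)
}

# ---- DP engine ------------------------------------------------------------

# 3^k x k matrix of colorings, colors coded g=0, o=1, r=2, first vertex most
# significant; row r encodes the coloring with canonical index r
state_matrix <- function(k) {
  if (k == 0) return(matrix(integer(), nrow = 1, ncol = 0))
  m <- matrix(0L, nrow = 3^k, ncol = k)
  for (j in seq_len(k))
    m[, j] <- rep(rep(0:2, each = 3^(k - j)), length.out = 3^k)
  m
}

# canonical base-3 index (1-based) of the columns `cols` of state matrix rows
state_index <- function(st, cols) {
  s <- length(cols)
  if (s == 0) return(rep(1L, nrow(st)))
  idx <- rep(1L, nrow(st))
  for (t in seq_len(s)) idx <- idx + st[, cols[t]] * 3L^(s - t)
  idx
}

# grouped maximum keeping the first (canonical) argmax
grouped_max_first <- function(values, groups, ngroups) {
  best <- rep(-Inf, ngroups)
  arg <- rep(NA_integer_, ngroups)
  keep <- !is.na(values)
  if (any(keep)) {
    v <- values[keep]; gidx <- groups[keep]; ridx <- which(keep)
    o <- order(gidx, -v, ridx)
    first <- !duplicated(gidx[o])
    best[gidx[o][first]] <- v[o][first]
    arg[gidx[o][first]] <- ridx[o][first]
  }
  list(best = best, arg = arg)
}

diet_engine <- function(g, rtd, target_width, w_eff, state_filter = NULL) {
  cap <- target_width + 1L
  keys <- as.character(bag_ids(rtd))
  verts_of <- lapply(rtd$bags, function(b) sort(b))
  names(verts_of) <- names(rtd$bags)
  eu <- g$edges$u; ev <- g$edges$v

  # bottom-up order: reverse BFS from the root
  ordkeys <- character(0); frontier <- rtd$root
  while (length(frontier) > 0) {
    ordkeys <- c(ordkeys, as.character(frontier))
    frontier <- unlist(rtd$children[as.character(frontier)], use.names = FALSE)
  }
  ordkeys <- rev(ordkeys)

  store <- new.env(parent = emptyenv())
  states_visited <- 0L

  for (key in ordkeys) {
    vx <- verts_of[[key]]
    k <- length(vx)
    St <- state_matrix(k)
    if (!is.null(state_filter)) {
      keep <- state_filter(St, vx)
      St <- St[keep, , drop = FALSE]
    }
    nr <- nrow(St)
    states_visited <- states_visited + nr
    greens <- if (k == 0) rep(0L, nr) else rowSums(St == 0L)
    kids <- rtd$children[[key]]
    choice <- matrix(NA_integer_, nrow = nr, ncol = length(kids))
    if (length(kids) == 0) {
      val <- ifelse(greens <= cap, 0, -Inf)
      assign(key, list(verts = vx, states = St, val = val, kids = kids,
                       choice = choice), envir = store)
      next
    }

    # per-child link tables
    linkrec <- vector("list", length(kids))
    for (j in seq_along(kids)) {
      ck <- as.character(kids[j])
      child <- get(ck, envir = store)
      cvx <- child$verts
      S <- sort(intersect(vx, cvx))
      s <- length(S)
      psC <- match(S, cvx); psP <- match(S, vx)
      newPos <- which(!(cvx %in% vx))
      Stc <- child$states
      allowed <- rep(TRUE, nrow(Stc))
      for (p in newPos) allowed <- allowed & (Stc[, p] != 2L)

      # A(fj) = child value + weight of green-green edges inside the child bag
      A <- child$val
      einC <- which(eu %in% cvx & ev %in% cvx)
      for (e in einC) {
        pu <- match(eu[e], cvx); pv <- match(ev[e], cvx)
        A <- A + w_eff[e] * ((Stc[, pu] == 0L) & (Stc[, pv] == 0L))
      }
      A[!allowed] <- -Inf
      sigC <- state_index(Stc, psC)
      gm <- grouped_max_first(A, sigC, 3L^s)

      # correction: edges green-green in both parent and child restrictions
      Sm <- state_matrix(s)
      einS <- which(eu %in% S & ev %in% S)
      if (length(einS) > 0) {
        GG <- matrix(0, nrow = 3L^s, ncol = length(einS))
        for (t in seq_along(einS)) {
          e <- einS[t]
          pu <- match(eu[e], S); pv <- match(ev[e], S)
          GG[, t] <- (Sm[, pu] == 0L) & (Sm[, pv] == 0L)
        }
        corrM <- tcrossprod(sweep(GG, 2, w_eff[einS], "*"), GG)
      } else {
        corrM <- matrix(0, nrow = 3L^s, ncol = 3L^s)
      }

      # Best[[fsig]]: per assignment-key max over compatible child restrictions
      nsig <- 3L^s
      Best <- vector("list", nsig)
      fkVal <- rep(-Inf, nsig); fkSig <- rep(NA_integer_, nsig)
      sigSeq <- seq_len(nsig)
      for (fs in sigSeq) {
        fcol <- Sm[fs, ]
        compat <- rep(TRUE, nsig)
        for (t in seq_len(s)) {
          if (fcol[t] == 0L) compat <- compat & (Sm[, t] != 1L)
          else if (fcol[t] == 2L) compat <- compat & (Sm[, t] == 2L)
        }
        sig_ok <- sigSeq[compat]
        vals <- gm$best[sig_ok] - corrM[fs, sig_ok]
        O <- which(fcol == 1L)
        if (length(O) == 0) {
          kk <- rep(0L, length(sig_ok))
        } else {
          kk <- rep(0L, length(sig_ok))
          for (t in seq_along(O))
            kk <- kk + (Sm[sig_ok, O[t]] != 2L) * 2L^(t - 1L)
        }
        gmk <- grouped_max_first(vals, kk + 1L, 2L^length(O))
        found <- which(!is.na(gmk$arg))
        Best[[fs]] <- list(key = found - 1L, val = gmk$best[found],
                           sig = sig_ok[gmk$arg[found]])
        full <- 2L^length(O) - 1L
        at <- match(full, found - 1L)
        if (!is.na(at)) {
          fkVal[fs] <- gmk$best[found][at]
          fkSig[fs] <- sig_ok[gmk$arg[found]][at]
        }
      }
      linkrec[[j]] <- list(S = S, argA = gm$arg, Best = Best,
                           fkVal = fkVal, fkSig = fkSig,
                           fsig = state_index(St, psP),
                           child_vx = cvx)
    }

    if (length(kids) == 1) {
      lr <- linkrec[[1]]
      val <- lr$fkVal[lr$fsig]
      sigchoice <- lr$fkSig[lr$fsig]
      choice[, 1] <- ifelse(is.na(sigchoice), NA_integer_, lr$argA[sigchoice])
    } else {
      val <- rep(-Inf, nr)
      for (srow in seq_len(nr)) {
        fcol <- St[srow, ]
        op <- which(fcol == 1L)
        olabs <- vx[op]
        holders <- lapply(olabs, function(u)
          which(vapply(seq_along(kids), function(j)
            u %in% linkrec[[j]]$child_vx, logical(1))))
        inkid <- vapply(holders, length, integer(1)) > 0
        olabs <- olabs[inkid]; holders <- holders[inkid]
        assigns <- if (length(olabs) == 0) list(integer(0)) else {
          gr <- expand.grid(rev(holders), KEEP.OUT.ATTRS = FALSE)
          gr <- gr[, rev(seq_along(holders)), drop = FALSE]
          lapply(seq_len(nrow(gr)), function(r) as.integer(gr[r, ]))
        }
        bestv <- -Inf; bestsig <- rep(NA_integer_, length(kids))
        for (m in assigns) {
          tot <- 0; sigs <- rep(NA_integer_, length(kids))
          for (j in seq_along(kids)) {
            lr <- linkrec[[j]]
            fs <- lr$fsig[srow]
            oinS <- which(Sm_colors(lr$S, vx, fcol) == 1L)
            keybits <- 0L
            if (length(oinS) > 0) {
              for (t in seq_along(oinS)) {
                u <- lr$S[oinS[t]]
                at <- match(u, olabs)
                if (!is.na(at) && m[at] == j)
                  keybits <- keybits + 2L^(t - 1L)
              }
            }
            rec <- lr$Best[[fs]]
            hit <- match(keybits, rec$key)
            if (is.na(hit)) { tot <- -Inf; break }
            tot <- tot + rec$val[hit]
            sigs[j] <- rec$sig[hit]
          }
          if (tot > bestv) { bestv <- tot; bestsig <- sigs }
        }
        val[srow] <- bestv
        for (j in seq_along(kids)) {
          if (!is.na(bestsig[j]))
            choice[srow, j] <- linkrec[[j]]$argA[bestsig[j]]
        }
      }
    }
    val[greens > cap] <- -Inf
    assign(key, list(verts = vx, states = St, val = val, kids = kids,
                     choice = choice), envir = store)
  }

  rootrec <- get(as.character(rtd$root), envir = store)
  objective <- rootrec$val[1]
  if (!is.finite(objective))
    stop("internal error: no feasible coloring found")   # all-red is always feasible

  coloring <- stats::setNames(vector("list", length(keys)), keys)
  walk <- function(key, srow) {
    rec <- get(key, envir = store)
    coloring[[key]] <<- stats::setNames(COLORS[rec$states[srow, ] + 1L],
                                        rec$verts)
    for (j in seq_along(rec$kids))
      walk(as.character(rec$kids[j]), rec$choice[srow, j])
  }
  walk(as.character(rtd$root), 1L)
  list(objective = objective, coloring = coloring,
       states_visited = states_visited)
}

# colors of the shared set S under the parent coloring (fcol over vx)
Sm_colors <- function(S, vx, fcol) fcol[match(S, vx)]

#' Apply a coloring: delete non-green occurrences, reattach lost vertices
#'
#' Bags keep only their green vertices. A vertex with no green occurrence
#' anywhere would disappear; it is reattached as a fresh singleton bag linked
#' to the root, so the result is a valid tree decomposition over all vertices
#' of the subgraph of realizable edges.
#'
#' @param rtd a `rooted_decomposition`.
#' @param coloring a valid full coloring of `rtd`.
#' @param g the [diet_graph()] the decomposition covers.
#' @return A [tree_decomposition()].
#' @export
apply_coloring <- function(rtd, coloring, g) {
  rep_ok <- check_coloring_validity(rtd, coloring)
  if (!rep_ok$ok)
    stop("invalid coloring: ", paste(rep_ok$messages, collapse = "; "))
  bags <- lapply(stats::setNames(names(rtd$bags), names(rtd$bags)),
                 function(key) {
                   f <- coloring[[key]]
                   names(f)[f == "g"]
                 })
  links <- rtd$links
  covered <- unique(unlist(bags, use.names = FALSE))
  missing <- setdiff(g$vertices, covered)
  nid <- max(bag_ids(rtd)) + 1L
  for (v in missing) {
    bags[[as.character(nid)]] <- v
    links <- rbind(links, c(rtd$root, nid))
    nid <- nid + 1L
  }
  tree_decomposition(bags, links)
}

#' Run independent diets over a descending list of target widths
#'
#' Each target width is dieted from the *original* decomposition, giving a
#' hierarchy of progressively coarser models; objectives are non-increasing
#' as the width shrinks.
#'
#' @param g a [diet_graph()].
#' @param rtd a `rooted_decomposition` of `g`.
#' @param widths strictly decreasing integer vector of target widths.
#' @param weight_mode,backbone_protect passed to [diet_params()].
#' @return A list of `diet_result`, one per width (empty list for no widths).
#' @export
diet_hierarchy <- function(g, rtd, widths, weight_mode = "count",
                           backbone_protect = FALSE) {
  widths <- as.integer(widths)
  if (length(widths) == 0) return(list())
  if (any(diff(widths) >= 0)) stop("widths must be strictly decreasing")
  lapply(widths, function(tw)
    tree_diet(g, rtd, diet_params(tw, weight_mode, backbone_protect)))
}
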