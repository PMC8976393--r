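#' Parse a PACE-style .gr graph file
#'
#' Reads the PACE 2017 `.gr` dialect: a header `p tw <n> <m>`, comment lines
#' starting with `c`, and edge lines `<u> <v>` with 1-based integer vertex
#' ids. As a documented extension, an optional third column gives the edge
#' weight. Duplicate edge lines collapse to one edge, the last weight winning.
#'
#' @param text a single string (or character vector of lines).
#' @return A [diet_graph()] with vertices `"1" .. "n"`.
#' @export
parse_graph_gr <- function(text) {
  lines <- split_lines(text)
  keep <- !grepl("^\\s*$", lines) & !grepl("^c($|\\s)", lines)
  lns <- which(keep)
  if (length(lns) == 0) stop("empty .gr input: no header line")
  header <- lines[lns[1]]
  hm <- regmatches(header,
                   regexec("^p\\s+tw\\s+(\\d+)\\s+(\\d+)\\s*$", header))[[1]]
  if (length(hm) != 3)
    stop("line ", lns[1], ": malformed header '", header,
         "' (expected 'p tw <n> <m>')")
  n <- as.integer(hm[2]); m <- as.integer(hm[3])
  eu <- ev <- integer(0); ew <- numeric(0)
  for (i in lns[-1]) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!(length(f) %in% c(2L, 3L)) || anyNA(suppressWarnings(as.numeric(f))))
      stop("line ", i, ": malformed edge line '", lines[i], "'")
    u <- suppressWarnings(as.integer(f[1])); v <- suppressWarnings(as.integer(f[2]))
    if (is.na(u) || is.na(v))
      stop("line ", i, ": non-integer vertex id in '", lines[i], "'")
    if (u < 1 || u > n || v < 1 || v > n)
      stop("line ", i, ": vertex id outside [1,", n, "] in '", lines[i], "'")
    if (u == v) stop("line ", i, ": self-loop on vertex ", u)
    w <- if (length(f) == 3) as.numeric(f[3]) else 1
    if (is.na(w) || w < 0) stop("line ", i, ": negative or invalid weight")
    eu <- c(eu, min(u, v)); ev <- c(ev, max(u, v)); ew <- c(ew, w)
  }
  # duplicates collapse; last weight wins
  key <- paste(eu, ev)
  last <- !duplicated(key, fromLast = TRUE)
  edges <- if (any(last))
    data.frame(u = as.character(eu[last]), v = as.character(ev[last]),
               weight = ew[last], backbone = FALSE, stringsAsFactors = FALSE)
  else NULL
  diet_graph(as.character(seq_len(n)), edges)
}

#' Write a graph in PACE-style .gr format
#'
#' Canonical output: edges sorted by endpoint ids, weights emitted as a third
#' column only when some weight differs from 1. `parse_graph_gr()` composed
#' with `write_graph_gr()` is the identity on graph content.
#'
#' @param g a [diet_graph()] whose vertex labels are the decimal integers
#'   `"1" .. "n"` (as produced by [parse_graph_gr()]).
#' @return A single string.
#' @export
write_graph_gr <- function(g) {
  stopifnot(inherits(g, "diet_graph"))
  n <- length(g$vertices)
  iu <- match(g$edges$u, g$vertices)
  iv <- match(g$edges$v, g$vertices)
  ord <- order(iu, iv)
  header <- sprintf("p tw %d %d", n, nrow(g$edges))
  if (nrow(g$edges) == 0) return(header)
  weighted <- any(g$edges$weight != 1)
  body <- if (weighted) {
    sprintf("%d %d %s", iu[ord], iv[ord],
            format_number(g$edges$weight[ord]))
  } else {
    sprintf("%d %d", iu[ord], iv[ord])
  }
  paste(c(header, body), collapse = "\n")
}

format_number <- function(x) {
  vapply(x, function(v) {
    if (v == round(v)) sprintf("%d", as.integer(round(v)))
    else format(v, scientific = FALSE)
  }, character(1))
}

split_lines <- function(text) {
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  as.character(text)
}
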