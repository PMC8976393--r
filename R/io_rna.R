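#' Build a structure graph from extended dot-bracket notation
#'
#' Positions 1..L become vertices "1".."L"; consecutive positions are joined
#' by backbone-flagged edges, and every matched bracket pair adds one
#' non-backbone edge. Bracket families `()`, `[]`, `{}`, `<>` and letter pairs
#' `Aa`..`Zz` each pair independently, so crossing (pseudoknotted) structures
#' are representable. An optional preceding sequence line is accepted and only
#' checked for length.
#'
#' A base pair between backbone-adjacent positions merges into the existing
#' backbone edge (the backbone flag wins, the larger weight is kept).
#'
#' @param text one structure line, optionally preceded by a sequence line.
#' @return A [diet_graph()].
#' @examples
#' g <- parse_rna_dotbracket("((..))")
#' graph_summary(g)   # 6 vertices, 5 backbone + 2 pair edges
#' @export
parse_rna_dotbracket <- function(text) {
  lines <- split_lines(text)
  lines <- lines[!grepl("^\\s*$", lines) & !grepl("^#", lines)]
  if (length(lines) == 0) stop("no structure line found")
  if (length(lines) > 2) stop("expected at most a sequence and a structure line")
  struct <- trimws(lines[length(lines)])
  if (length(lines) == 2) {
    seqline <- trimws(lines[1])
    if (nchar(seqline) != nchar(struct))
      stop("sequence length (", nchar(seqline),
           ") does not match structure length (", nchar(struct), ")")
  }
  chars <- strsplit(struct, "")[[1]]
  L <- length(chars)
  openers <- c("(", "[", "{", "<", LETTERS)
  closers <- c(")", "]", "}", ">", letters)
  stacks <- rep(list(integer()), length(openers))
  pu <- pv <- integer(0)
  for (i in seq_len(L)) {
    ch <- chars[i]
    if (ch == ".") next
    io <- match(ch, openers)
    ic <- match(ch, closers)
    if (!is.na(io)) {
      stacks[[io]] <- c(stacks[[io]], i)
    } else if (!is.na(ic)) {
      st <- stacks[[ic]]
      if (length(st) == 0)
        stop("unbalanced brackets: unmatched '", ch, "' at position ", i)
      pu <- c(pu, st[length(st)]); pv <- c(pv, i)
      stacks[[ic]] <- st[-length(st)]
    } else {
      stop("invalid structure character '", ch, "' at position ", i)
    }
  }
  open_left <- vapply(stacks, length, integer(1))
  if (any(open_left > 0))
    stop("unbalanced brackets: ", sum(open_left), " unmatched opener(s)")
  rna_graph(L, pu, pv)
}

#' Build a structure graph from bpseq format
#'
#' Standard bpseq: one line `<i> <base> <j>` per position, 1-based, with
#' `j = 0` meaning unpaired. Lines starting with `#` are comments. The
#' positions must cover 1..L exactly once and the pairing must be symmetric.
#' The resulting graph has the same semantics as [parse_rna_dotbracket()].
#'
#' @param text bpseq content.
#' @return A [diet_graph()].
#' @export
parse_rna_bpseq <- function(text) {
  lines <- split_lines(text)
  lines <- lines[!grepl("^\\s*$", lines) & !grepl("^#", lines)]
  if (length(lines) == 0) stop("empty bpseq input")
  f <- strsplit(trimws(lines), "\\s+")
  if (any(vapply(f, length, integer(1)) != 3))
    stop("each bpseq line must be '<i> <base> <j>'")
  i <- suppressWarnings(as.integer(vapply(f, `[`, character(1), 1)))
  j <- suppressWarnings(as.integer(vapply(f, `[`, character(1), 3)))
  if (anyNA(i) || anyNA(j)) stop("non-integer position in bpseq input")
  L <- length(i)
  if (!setequal(i, seq_len(L)) || anyDuplicated(i))
    stop("bpseq positions must cover 1..", L, " exactly once")
  partner <- integer(L); partner[i] <- j
  if (any(partner < 0 | partner > L)) stop("pairing partner outside 1..", L)
  sel <- which(partner > 0)
  if (any(partner[sel] == sel)) stop("position paired with itself")
  if (any(partner[partner[sel]] != sel))
    stop("asymmetric pairing: i pairs j but j does not pair i")
  pairs <- which(partner > seq_len(L))
  rna_graph(L, pairs, partner[pairs])
}

# shared builder: backbone path 1..L plus base-pair edges, merging a pair
# between adjacent positions into the backbone edge
rna_graph <- function(L, pu, pv, pw = NULL) {
  if (is.null(pw)) pw <- rep(1, length(pu))
  eu <- ev <- integer(0); ew <- numeric(0); eb <- logical(0)
  if (L >= 2) {
    eu <- seq_len(L - 1); ev <- eu + 1L
    ew <- rep(1, L - 1); eb <- rep(TRUE, L - 1)
  }
  if (length(pu) > 0) {
    lo <- pmin(pu, pv); hi <- pmax(pu, pv)
    adj <- hi == lo + 1L
    for (k in which(adj)) {          # merge into backbone edge, weight = max
      at <- which(eu == lo[k])
      ew[at] <- max(ew[at], pw[k])
    }
    eu <- c(eu, lo[!adj]); ev <- c(ev, hi[!adj])
    ew <- c(ew, pw[!adj]); eb <- c(eb, rep(FALSE, sum(!adj)))
  }
  diet_graph(as.character(seq_len(L)),
             data.frame(u = as.character(eu), v = as.character(ev),
                        weight = ew, backbone = eb, stringsAsFactors = FALSE))
}
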