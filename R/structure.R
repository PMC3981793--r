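# Secondary structures as non-crossing base-pair sets with a dot-bracket
# form, plus the base-pair distance used to score structural change.

#' Construct a secondary structure from a base-pair set
#'
#' Validates that each index appears in at most one pair, that no two pairs
#' cross, and (optionally) that every hairpin loop has at least three
#' unpaired bases.  Canonicity of the pairs is a property of a structure
#' *relative to a sequence* and is checked by [score_structure()] instead.
#'
#' @param pairs two-column integer matrix of (i, j) pairs, 1-based; a
#'   zero-row matrix or `NULL` gives the open chain.
#' @param n sequence length.
#' @param check_min_loop enforce the minimum hairpin loop of 3 unpaired
#'   bases (`j - i - 1 >= 3`).  Parsed output of external engines is
#'   accepted without this check.
#' @return An object of class `rna_structure` with fields `n`, `pairs`
#'   (sorted by `i`) and `dotbracket`.
#' @examples
#' secondary_structure(rbind(c(1, 9), c(2, 8)), 9)
#' @export
secondary_structure <- function(pairs, n, check_min_loop = TRUE) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  n <- as.integer(n)
  if (is.null(pairs) || length(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2)
  }
  if (nrow(pairs)) {
    swap <- pairs[, 1] > pairs[, 2]
    pairs[swap, ] <- pairs[swap, 2:1]
    if (any(pairs[, 1] < 1) || any(pairs[, 2] > n) || any(pairs[, 1] == pairs[, 2]))
      stop("pair indices must satisfy 1 <= i < j <= n")
    idx <- c(pairs)
    if (anyDuplicated(idx))
      stop(sprintf("index %d appears in more than one pair", idx[duplicated(idx)][1]))
    if (check_min_loop && any(pairs[, 2] - pairs[, 1] - 1 < 3)) {
      bad <- which(pairs[, 2] - pairs[, 1] - 1 < 3)[1]
      stop(sprintf("pair (%d,%d) violates the minimum hairpin loop of 3 unpaired bases",
                   pairs[bad, 1], pairs[bad, 2]))
    }
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    # crossing check: sweep open pairs with a stack
    open <- integer(0) # j of currently open pairs
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      while (length(open) && open[length(open)] < i) open <- open[-length(open)]
      if (length(open) && j > open[length(open)])
        stop(sprintf("pairs cross at (%d,%d)", i, j))
      open <- c(open, j)
    }
  }
  db <- rep(".", n)
  db[pairs[, 1]] <- "("
  db[pairs[, 2]] <- ")"
  structure(
    list(n = n, pairs = pairs, dotbracket = paste(db, collapse = "")),
    class = "rna_structure"
  )
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("<rna_structure> %d nt, %d pairs\n%s\n", x$n, nrow(x$pairs), x$dotbracket))
  invisible(x)
}

#' Parse a dot-bracket string
#'
#' Matched-parenthesis pairing over `.`, `(` and `)`.  Only balance is
#' enforced: minimum-loop and canonicity checks are deliberately skipped so
#' that output of external folding engines is never rejected beyond
#' well-formedness.
#'
#' @param s dot-bracket string.
#' @return An `rna_structure`.
#' @examples
#' parse_dotbracket("((...))")
#' @export
parse_dotbracket <- function(s) {
  if (!is.character(s) || length(s) != 1L)
    stop("`s` must be a single character string")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n == 0L) stop("empty dot-bracket string")
  bad <- which(!ch %in% c(".", "(", ")"))
  if (length(bad))
    stop(sprintf("invalid character '%s' at position %d (expected '.', '(' or ')')",
                 ch[bad[1]], bad[1]))
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (k in seq_len(n)) {
    if (ch[k] == "(") {
      open <- c(open, k)
    } else if (ch[k] == ")") {
      if (!length(open))
        stop(sprintf("unbalanced dot-bracket: unmatched ')' at position %d", k))
      pairs <- rbind(pairs, c(open[length(open)], k))
      open <- open[-length(open)]
    }
  }
  if (length(open))
    stop(sprintf("unbalanced dot-bracket: unmatched '(' at position %d", open[1]))
  secondary_structure(pairs, n, check_min_loop = FALSE)
}

#' Base-pair distance between two structures
#'
#' The size of the symmetric difference of the two base-pair sets: the
#' number of pairs present in exactly one of the two structures.  This is
#' the standard base-pair distance and the quantity a thermometer scan
#' records per window.
#'
#' @param a,b `rna_structure` objects for sequences of equal length.
#' @return Nonnegative integer.
#' @examples
#' bp_distance(parse_dotbracket("((...))"), parse_dotbracket(".(...)."))
#' @export
bp_distance <- function(a, b) {
  if (!inherits(a, "rna_structure") || !inherits(b, "rna_structure"))
    stop("`a` and `b` must be rna_structure objects")
  if (a$n != b$n)
    stop(sprintf("structures describe sequences of different lengths (%d vs %d)", a$n, b$n))
  key <- function(s) s$pairs[, 1] * (s$n + 1) + s$pairs[, 2]
  ka <- key(a)
  kb <- key(b)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}
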