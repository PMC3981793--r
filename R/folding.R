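# Structure prediction under the reduced nearest-neighbor model: structure
# scoring (the single definition of E(S) shared by the dynamic program and
# the brute-force oracle), exhaustive enumeration for small sequences, MFE
# folding, the partition function with base-pair probabilities, centroid
# structures, and the engine dispatch used by scans.

.canonical_pair <- function(a, b) {
  paste0(a, b) %in% PAIR_TYPES
}

# decompose a structure into loops: for each pair, its directly enclosed
# child pairs; returns list with parent index per pair (0 = exterior)
.structure_children <- function(pairs) {
  m <- nrow(pairs)
  children <- vector("list", m + 1L) # children[[k+1]] = children of pair k
  if (m == 0L) return(children)
  stack <- integer(0) # indices of open pairs, innermost last
  for (r in seq_len(m)) { # pairs sorted by i
    i <- pairs[r, 1]
    while (length(stack) && pairs[stack[length(stack)], 2] < i)
      stack <- stack[-length(stack)]
    parent <- if (length(stack)) stack[length(stack)] else 0L
    children[[parent + 1L]] <- c(children[[parent + 1L]], r)
    stack <- c(stack, r)
  }
  children
}

#' Free energy of a given structure on a given sequence
#'
#' The single definition of the model's structure energy:
#' stack terms over adjacent pairs, hairpin-loop and internal/bulge-loop
#' terms; multibranch loops and exterior unpaired bases contribute zero,
#' so the open chain scores exactly 0.
#'
#' @param seq an [rna_sequence].
#' @param s an `rna_structure` valid for `seq` (canonical pairs, minimum
#'   hairpin loop); violations are validation errors.
#' @param t temperature in degrees C (or a [temperature()] object).
#' @param params an `energy_params` object.
#' @return Energy in kcal/mol.
#' @export
score_structure <- function(seq, s, t, params = default_energy_params()) {
  stopifnot(inherits(seq, "rna_sequence"), inherits(s, "rna_structure"))
  t <- as_temperature(t)
  if (s$n != seq$length)
    stop(sprintf("structure length %d does not match sequence length %d", s$n, seq$length))
  pairs <- s$pairs
  if (nrow(pairs) == 0L) return(0)
  res <- strsplit(seq$residues, "", fixed = TRUE)[[1]]
  ptype <- paste0(res[pairs[, 1]], res[pairs[, 2]])
  badp <- which(!ptype %in% PAIR_TYPES)
  if (length(badp))
    stop(sprintf("non-canonical pair (%d,%d): %s",
                 pairs[badp[1], 1], pairs[badp[1], 2], ptype[badp[1]]))
  if (any(pairs[, 2] - pairs[, 1] - 1 < 3))
    stop("structure violates the minimum hairpin loop of 3 unpaired bases")
  children <- .structure_children(pairs)
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    kids <- children[[r + 1L]]
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (length(kids) == 0L) {
      e <- e + loop_energy("hairpin", j - i - 1, t, params)
    } else if (length(kids) == 1L) {
      k <- pairs[kids, 1]; l <- pairs[kids, 2]
      if (k == i + 1 && l == j - 1) {
        e <- e + stack_energy(paste0(ptype[r], "/", ptype[kids]), t, params)
      } else {
        e <- e + loop_energy("internal", (k - i - 1) + (j - l - 1), t, params)
      }
    }
    # >= 2 children: multibranch loop, zero beyond its branches
  }
  e
}

#' Enumerate all valid secondary structures of a short sequence
#'
#' Exhaustive, duplicate-free enumeration (including the open chain) of
#' every structure satisfying the structural invariants: canonical pairs,
#' no shared indices, no crossings, minimum hairpin loop of 3.  This is the
#' brute-force test oracle for the dynamic programs and is guarded against
#' combinatorial blowup.
#'
#' @param seq an [rna_sequence] of length at most 20.
#' @return List of `rna_structure` objects.
#' @export
enumerate_structures <- function(seq) {
  stopifnot(inherits(seq, "rna_sequence"))
  n <- seq$length
  if (n > 20)
    stop("enumerate_structures is limited to sequences of length <= 20")
  res <- strsplit(seq$residues, "", fixed = TRUE)[[1]]
  memo <- new.env(parent = emptyenv())
  # structures on [i..j] as lists of pair matrices; condition on the fate
  # of position i (unpaired, or paired to each feasible k) for uniqueness
  enum <- function(i, j) {
    if (j - i < 4) return(list(matrix(integer(0), ncol = 2)))
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- enum(i + 1, j)
    for (k in (i + 4):j) {
      if (!.canonical_pair(res[i], res[k])) next
      inner <- enum(i + 1, k - 1)
      rest <- if (k < j) enum(k + 1, j) else list(matrix(integer(0), ncol = 2))
      for (a in inner) for (b in rest)
        out <- c(out, list(rbind(c(i, k), a, b)))
    }
    memo[[key]] <- out
    out
  }
  lapply(enum(1L, n), secondary_structure, n = n)
}

.fold_result <- function(structure, energy, t, mode) {
  structure(
    list(structure = structure, energy = energy, temperature = t, mode = mode),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> %s at %g C, %.3f kcal/mol\n%s\n",
              x$mode, x$temperature$celsius, x$energy, x$structure$dotbracket))
  invisible(x)
}

.mate_to_pairs <- function(mate) {
  i <- which(mate > seq_along(mate))
  cbind(i, mate[i], deparse.level = 0)
}

#' Minimum-free-energy structure by dynamic programming
#'
#' Zuker-style recursion over the reduced model, with a deterministic
#' traceback (ties resolved toward hairpin closure, then stacking, then the
#' smallest interior loop, then the bifurcation with the smallest split
#' point).  The open chain at energy 0 is always a candidate, so the
#' returned energy is never positive.
#'
#' @inheritParams score_structure
#' @return A `fold_result` with `mode = "mfe"`, whose `energy` equals
#'   [score_structure()] of its structure exactly.
#' @export
fold_mfe <- function(seq, t, params = default_energy_params()) {
  stopifnot(inherits(seq, "rna_sequence"))
  t <- as_temperature(t)
  r <- mfe_fold_cpp(.base_codes(seq$residues), t$kelvin, .cpp_params(params))
  s <- secondary_structure(.mate_to_pairs(r$mate), seq$length)
  .fold_result(s, r$energy, t, "mfe")
}

#' Partition function and equilibrium base-pair probabilities
#'
#' McCaskill-style inside-outside recursions over the same model (and the
#' same interior-loop size cap) as [fold_mfe()]:
#' `Z = sum over structures S of exp(-E(S) / (R T))` and
#' `p(i,j) = sum over S containing (i,j) of exp(-E(S)/(R T)) / Z`.
#'
#' @inheritParams score_structure
#' @return A list with `Z` (dimensionless) and `probs`, a
#'   `pair_prob_matrix` (fields `n` and the upper-triangular matrix `p`).
#' @export
partition_function <- function(seq, t, params = default_energy_params()) {
  stopifnot(inherits(seq, "rna_sequence"))
  t <- as_temperature(t)
  r <- partition_cpp(.base_codes(seq$residues), t$kelvin, .cpp_params(params))
  probs <- structure(list(n = seq$length, p = r$p), class = "pair_prob_matrix")
  list(Z = r$Z, probs = probs)
}

#' @export
print.pair_prob_matrix <- function(x, ...) {
  cat(sprintf("<pair_prob_matrix> %d nt, %d pairs with p > 0.01\n",
              x$n, sum(x$p > 0.01)))
  invisible(x)
}

#' Centroid structure from base-pair probabilities
#'
#' The classical centroid estimator: all pairs with equilibrium probability
#' above 1/2.  In a non-crossing ensemble no two conflicting pairs can both
#' exceed probability 1/2, so the set is always a valid structure.
#'
#' @param probs a `pair_prob_matrix` from [partition_function()].
#' @return An `rna_structure`.
#' @export
centroid_structure <- function(probs) {
  stopifnot(inherits(probs, "pair_prob_matrix"))
  sel <- which(probs$p > 0.5, arr.ind = TRUE)
  sel <- sel[sel[, 1] < sel[, 2], , drop = FALSE]
  secondary_structure(sel, probs$n, check_min_loop = FALSE)
}

#' Fold a sequence with a chosen mode and engine
#'
#' Dispatches to the builtin engine ([fold_mfe()], or
#' [partition_function()] + [centroid_structure()] for centroid mode) or to
#' a registered external engine adapter (see [register_engine()]), whose
#' dot-bracket output is parsed into the same `fold_result` contract.
#'
#' @inheritParams score_structure
#' @param mode `"mfe"` or `"centroid"`.
#' @param engine engine name; `"builtin"` is always available.
#' @return A `fold_result`.
#' @export
fold <- function(seq, t, mode = c("mfe", "centroid"), engine = "builtin",
                 params = default_energy_params()) {
  stopifnot(inherits(seq, "rna_sequence"))
  mode <- match.arg(mode)
  t <- as_temperature(t)
  if (identical(engine, "builtin")) {
    if (mode == "mfe") return(fold_mfe(seq, t, params))
    pf <- partition_function(seq, t, params)
    s <- centroid_structure(pf$probs)
    energy <- score_structure(seq, s, t, params)
    return(.fold_result(s, energy, t, "centroid"))
  }
  fun <- get_engine(engine)
  raw <- tryCatch(
    fun(seq$residues, t$celsius, mode),
    error = function(e) stop(sprintf("engine '%s' failed: %s", engine,
                                     conditionMessage(e)))
  )
  if (!is.list(raw) || is.null(raw$dotbracket))
    stop(sprintf("engine '%s' returned no dot-bracket output", engine))
  s <- tryCatch(
    parse_dotbracket(raw$dotbracket),
    error = function(e) stop(sprintf(
      "engine '%s' returned unparseable output: %s\nraw output: %s",
      engine, conditionMessage(e), raw$dotbracket
    ))
  )
  if (s$n != seq$length)
    stop(sprintf("engine '%s' returned a structure of length %d for a %d-nt sequence",
                 engine, s$n, seq$length))
  energy <- if (is.null(raw$energy)) NA_real_ else raw$energy
  .fold_result(s, energy, t, mode)
}
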