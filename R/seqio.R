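#' Construct a validated RNA sequence
#'
#' An `rna_sequence` is an identifier plus a residue string over the RNA
#' alphabet `A`, `C`, `G`, `U`.  Input is normalized with
#' [normalize_sequence()]: whitespace is stripped, lower case is raised and
#' DNA `T` is converted to `U`.  Ambiguity codes (`N`, `R`, ...) are
#' rejected: a folding call on an ambiguous window would silently change
#' meaning, so failing loudly is preferred.
#'
#' @param id free-text record identifier.
#' @param residues character scalar of residues (RNA or DNA, any case).
#' @return An object of class `rna_sequence` with fields `id`, `residues`
#'   and `length`.
#' @examples
#' rna_sequence("ex", "acgt")
#' @export
rna_sequence <- function(id, residues) {
  if (!is.character(id) || length(id) != 1L)
    stop("`id` must be a single character string")
  res <- normalize_sequence(residues)
  structure(
    list(id = id, residues = res, length = nchar(res)),
    class = "rna_sequence"
  )
}

#' @export
print.rna_sequence <- function(x, ...) {
  shown <- if (x$length > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<rna_sequence> %s (%d nt)\n%s\n", x$id, x$length, shown))
  invisible(x)
}

#' Normalize a raw residue string to the RNA alphabet
#'
#' Strips whitespace, uppercases, and converts `T` to `U`.  Any other
#' character is a validation error reporting its position (in the
#' whitespace-stripped string) and identity.
#'
#' @param raw character scalar.
#' @return Character scalar over `A`, `C`, `G`, `U`.
#' @examples
#' normalize_sequence("ac gt\n")  # "ACGU"
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L)
    stop("`raw` must be a single character string")
  s <- gsub("[[:space:]]", "", raw)
  if (!nzchar(s)) stop("sequence is empty after removing whitespace")
  u <- toupper(s)
  bad <- regexpr("[^ACGUT]", u)
  if (bad > 0) {
    ch <- substr(u, bad, bad)
    stop(sprintf(
      "invalid character '%s' at position %d: only A/C/G/U (and T, converted to U) are accepted; resolve ambiguity codes before folding",
      ch, bad
    ))
  }
  chartr("T", "U", u)
}

#' Read RNA sequences from a FASTA file
#'
#' Reads every record of a FASTA file (arbitrary line wrapping) and
#' normalizes each sequence (see [normalize_sequence()]).  DNA input is
#' accepted and converted.  Each record is independent; downstream scans
#' namespace their outputs by record id.
#'
#' @param path path to a FASTA file.
#' @return A list of [rna_sequence] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("cannot parse FASTA file %s: %s",
                                     path, conditionMessage(e)))
  )
  if (length(set) == 0L) stop(sprintf("FASTA file %s contains no records", path))
  ids <- names(set)
  seqs <- unname(as.character(set))
  lapply(seq_along(seqs), function(k) {
    id <- if (is.null(ids) || !nzchar(ids[k])) sprintf("record_%d", k) else ids[k]
    if (!nzchar(seqs[k]))
      stop(sprintf("record '%s' in %s has an empty sequence", id, path))
    tryCatch(
      rna_sequence(id, seqs[k]),
      error = function(e) stop(sprintf("record '%s': %s", id, conditionMessage(e)))
    )
  })
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs an [rna_sequence] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  set <- Biostrings::BStringSet(vapply(seqs, function(s) s$residues, character(1)))
  names(set) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
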