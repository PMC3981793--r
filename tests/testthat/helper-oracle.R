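# Test helpers: random sequence generation, the brute-force energy /
# Boltzmann oracles built on enumerate_structures() + score_structure(),
# an independent structure-counting recursion, and a pool of random
# structures for metric tests.

random_rna <- function(n) {
  rna_sequence("rand", paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                             collapse = ""))
}

# brute-force minimum over the exhaustively enumerated ensemble
brute_min_energy <- function(seq, t, params = default_energy_params()) {
  en <- vapply(enumerate_structures(seq), function(s)
    score_structure(seq, s, t, params), numeric(1))
  min(en)
}

# direct Boltzmann summation over the enumerated ensemble
brute_boltzmann <- function(seq, t, params = default_energy_params()) {
  tt <- temperature(if (inherits(t, "rna_temperature")) t$celsius else t)
  structs <- enumerate_structures(seq)
  en <- vapply(structs, function(s) score_structure(seq, s, tt, params), numeric(1))
  w <- exp(-en / (GAS_CONSTANT * tt$kelvin))
  Z <- sum(w)
  n <- seq$length
  p <- matrix(0, n, n)
  for (k in seq_along(structs)) {
    pr <- structs[[k]]$pairs
    if (nrow(pr)) {
      for (r in seq_len(nrow(pr))) {
        p[pr[r, 1], pr[r, 2]] <- p[pr[r, 1], pr[r, 2]] + w[k]
      }
    }
  }
  list(Z = Z, p = p / Z)
}

# independent recursive structure count (counts, never lists): the number
# of valid structures on [i..j], conditioning on the fate of position i
count_structures <- function(residues) {
  res <- strsplit(residues, "", fixed = TRUE)[[1]]
  n <- length(res)
  canon <- function(a, b) paste0(a, b) %in% PAIR_TYPES
  memo <- new.env(parent = emptyenv())
  cnt <- function(i, j) {
    if (j - i < 4) return(1)
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    total <- cnt(i + 1, j)
    for (k in (i + 4):j) {
      if (canon(res[i], res[k]))
        total <- total + cnt(i + 1, k - 1) * (if (k < j) cnt(k + 1, j) else 1)
    }
    memo[[key]] <- total
    total
  }
  cnt(1, n)
}

# pool of random valid structures of a common length, drawn from the
# enumerated ensemble of one structured sequence
structure_pool <- function() {
  if (is.null(the$pool)) {
    seqs <- list(rna_sequence("p1", "GGCGAAACGCCAUA"),
                 rna_sequence("p2", "GCAGUAAACUGCAA"))
    the$pool <- unlist(lapply(seqs, enumerate_structures), recursive = FALSE)
  }
  the$pool
}
the <- new.env(parent = emptyenv())

make_fasta <- function(records, path = tempfile(fileext = ".fa"), wrap = 60) {
  lines <- unlist(lapply(names(records), function(id) {
    s <- records[[id]]
    c(paste0(">", id),
      substring(s, seq(1, nchar(s), wrap), pmin(seq(1, nchar(s), wrap) + wrap - 1, nchar(s))))
  }))
  writeLines(lines, path)
  path
}
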