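# Seeded generator of synthetic thermometer test sequences: a hairpin whose
# stability flips between two temperatures, embedded at a known location in
# low-structure flanks.  The melting temperature is the closed-form root of
# the designed hairpin's total dG(T) = dH_tot - T * dS_tot under the
# builtin model -- a testable surrogate for experimental melting, with no
# claim of biophysical accuracy.

#' Specification of a synthetic RNA thermometer
#'
#' @param stem_length stem length in base pairs (>= 2; the sentinel 0 asks
#'   for a control record: flanks only, no hairpin, no annotation).
#' @param loop_length hairpin loop length in unpaired bases (>= 3).
#' @param tm_low,tm_high temperature bracket (degrees C) that must strictly
#'   contain the hairpin's melting temperature; scans of the record are
#'   meant to run at these two temperatures.
#' @param flank5,flank3 lengths of the 5' and 3' low-structure flanks.
#' @param seed RNG seed; generation is fully reproducible from it.
#' @return An object of class `thermometer_spec`.
#' @export
thermometer_spec <- function(stem_length = 10, loop_length = 6,
                             tm_low = 37, tm_high = 55,
                             flank5 = 87, flank3 = 87, seed = 1) {
  if (stem_length != 0 && stem_length < 2)
    stop("`stem_length` must be >= 2 (or 0 for a control record)")
  if (loop_length < 3) stop("`loop_length` must be >= 3")
  if (tm_low >= tm_high) stop("`tm_low` must be below `tm_high`")
  if (flank5 < 0 || flank3 < 0) stop("flank lengths must be nonnegative")
  structure(
    list(stem_length = as.integer(stem_length), loop_length = as.integer(loop_length),
         tm_low = tm_low, tm_high = tm_high,
         flank5 = as.integer(flank5), flank3 = as.integer(flank3),
         seed = as.integer(seed)),
    class = "thermometer_spec"
  )
}

# total dH and effective dS of a fully paired hairpin given its ordered
# pair types (outside -> inside) and loop size
.hairpin_thermo <- function(pair_types, loop_length, params) {
  dH <- 0
  dS <- 0
  for (k in seq_len(length(pair_types) - 1L)) {
    dH <- dH + params$stack_dH[pair_types[k], pair_types[k + 1L]]
    dS <- dS + params$stack_dS[pair_types[k], pair_types[k + 1L]]
  }
  size <- min(loop_length, 30L)
  g37 <- params$hairpin_dG37[as.character(size)]
  if (loop_length > 30L)
    g37 <- g37 + 1.75 * GAS_CONSTANT * .T37 * log(loop_length / 30)
  dS <- dS - unname(g37) / .T37
  list(dH = dH, dS = dS)
}

# deterministic arrangement of a stem composition: GC pairs outermost
# (alternating orientation), then AU, then GU nearest the loop
.arrange_stem <- function(stem, ngc, ngu) {
  nau <- stem - ngc - ngu
  alt <- function(a, b, n) if (n <= 0) character(0) else
    rep(c(a, b), length.out = n)
  c(alt("GC", "CG", ngc), alt("AU", "UA", nau), alt("GU", "UG", ngu))
}

#' Design a hairpin whose melting temperature lies in a given bracket
#'
#' Searches stem pair compositions (numbers of GC, AU and GU pairs in a
#' fixed arrangement) for the one whose melting temperature
#' `Tm = dH_tot / dS_tot` under the builtin model falls strictly inside
#' `(tm_low, tm_high)`, preferring the composition closest to the bracket
#' midpoint.  Loop bases are chosen from whichever of A or C has fewer
#' pairing partners in the stem.
#'
#' @param spec a [thermometer_spec()] with `stem_length >= 2`.
#' @param params an `energy_params` object.
#' @return An object of class `hairpin_design`: `sequence` (the stem-loop
#'   string), `pairs` (the designed base pairs, 1-based within the
#'   stem-loop), `predicted_tm` (degrees C), `dH`, `dS`.
#' @export
design_hairpin <- function(spec, params = default_energy_params()) {
  stopifnot(inherits(spec, "thermometer_spec"))
  stem <- spec$stem_length
  if (stem < 2) stop("`design_hairpin` needs a stem of at least 2 pairs")
  mid <- (spec$tm_low + spec$tm_high) / 2
  best <- NULL
  tms <- c()
  for (ngc in 0:stem) {
    for (ngu in 0:(stem - ngc)) {
      pt <- .arrange_stem(stem, ngc, ngu)
      th <- .hairpin_thermo(pt, spec$loop_length, params)
      if (th$dH >= 0 || th$dS >= 0) next
      tmC <- th$dH / th$dS - 273.15
      tms <- c(tms, tmC)
      if (tmC <= spec$tm_low || tmC >= spec$tm_high) next
      if (is.null(best) || abs(tmC - mid) < abs(best$tm - mid))
        best <- list(pt = pt, tm = tmC, dH = th$dH, dS = th$dS)
    }
  }
  if (is.null(best)) {
    rng <- if (length(tms)) sprintf("%.1f to %.1f", min(tms), max(tms)) else "none"
    stop(sprintf(
      "no stem composition of %d pairs has a melting temperature inside (%g, %g) C; achievable range: %s C",
      stem, spec$tm_low, spec$tm_high, rng
    ))
  }
  left <- substr(best$pt, 1, 1)
  right <- rev(substr(best$pt, 2, 2))
  stem_chars <- c(left, right)
  loop_base <- if (sum(stem_chars == "U") <= sum(stem_chars == "G")) "A" else "C"
  seq <- paste(c(left, rep(loop_base, spec$loop_length), right), collapse = "")
  len <- 2L * stem + spec$loop_length
  pairs <- cbind(seq_len(stem), len + 1L - seq_len(stem))
  structure(
    list(sequence = seq, pairs = pairs, predicted_tm = best$tm,
         dH = best$dH, dS = best$dS),
    class = "hairpin_design"
  )
}

#' @export
print.hairpin_design <- function(x, ...) {
  cat(sprintf("<hairpin_design> %s\npredicted Tm %.1f C (dH %.1f, dS %.4f)\n",
              x$sequence, x$predicted_tm, x$dH, x$dS))
  invisible(x)
}

# low-structure flank: rejection-sample until the standalone MFE at tm_low
# is >= -0.5 kcal/mol
.sample_flank <- function(len, tm_low, params, max_attempts = 1000L) {
  if (len == 0L) return("")
  alphabet <- c("A", "C", "G", "U")
  probs <- c(0.35, 0.35, 0.15, 0.15)
  for (attempt in seq_len(max_attempts)) {
    s <- paste(sample(alphabet, len, replace = TRUE, prob = probs), collapse = "")
    if (len < 5L) return(s)
    e <- fold_mfe(rna_sequence("flank", s), tm_low, params)$energy
    if (e >= -0.5) return(s)
  }
  stop(sprintf(
    "could not sample a low-structure flank of %d nt in %d attempts; try shorter flanks",
    len, max_attempts
  ))
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic thermometer (or control) record
#'
#' Concatenates seeded low-structure flanks around the designed stem-loop
#' and records the hairpin's 1-based inclusive interval.  With the control
#' sentinel (`stem_length = 0`) only flanks are generated and there is no
#' annotation.  As a post-condition, the isolated hairpin interval folds
#' into the designed stem at `tm_low` and into the open chain at
#' `tm_high`, so the base-pair distance across the two temperatures is at
#' least `stem_length`.
#'
#' @inheritParams design_hairpin
#' @param spec a [thermometer_spec()].
#' @return An object of class `synthetic_record`: `sequence` (an
#'   [rna_sequence]), `thermometer_interval` (`c(start, end)` or `NULL`
#'   for controls), `predicted_tm` (`NA` for controls) and `spec`.
#' @export
make_record <- function(spec, params = default_energy_params()) {
  stopifnot(inherits(spec, "thermometer_spec"))
  .with_seed(spec$seed, {
    if (spec$stem_length == 0L) {
      f5 <- .sample_flank(spec$flank5, spec$tm_low, params)
      f3 <- .sample_flank(spec$flank3, spec$tm_low, params)
      seq <- rna_sequence(
        sprintf("synth_control_seed%d", spec$seed), paste0(f5, f3)
      )
      return(structure(
        list(sequence = seq, thermometer_interval = NULL,
             predicted_tm = NA_real_, spec = spec),
        class = "synthetic_record"
      ))
    }
    hp <- design_hairpin(spec, params)
    f5 <- .sample_flank(spec$flank5, spec$tm_low, params)
    f3 <- .sample_flank(spec$flank3, spec$tm_low, params)
    seq <- rna_sequence(
      sprintf("synth_thermo_stem%d_seed%d", spec$stem_length, spec$seed),
      paste0(f5, hp$sequence, f3)
    )
    interval <- c(spec$flank5 + 1L, spec$flank5 + nchar(hp$sequence))
    # post-condition: the isolated hairpin is folded cold and open hot
    iso <- rna_sequence("hairpin", hp$sequence)
    cold <- fold_mfe(iso, spec$tm_low, params)$structure
    hot <- fold_mfe(iso, spec$tm_high, params)$structure
    if (bp_distance(cold, hot) < spec$stem_length)
      stop(sprintf(
        "designed hairpin does not melt between %g and %g C (distance %d < stem %d); widen the bracket",
        spec$tm_low, spec$tm_high, bp_distance(cold, hot), spec$stem_length
      ))
    structure(
      list(sequence = seq, thermometer_interval = interval,
           predicted_tm = hp$predicted_tm, spec = spec),
      class = "synthetic_record"
    )
  })
}

#' @export
print.synthetic_record <- function(x, ...) {
  if (is.null(x$thermometer_interval)) {
    cat(sprintf("<synthetic_record> control %s (%d nt)\n",
                x$sequence$id, x$sequence$length))
  } else {
    cat(sprintf("<synthetic_record> %s (%d nt), hairpin at [%d, %d], predicted Tm %.1f C\n",
                x$sequence$id, x$sequence$length,
                x$thermometer_interval[1], x$thermometer_interval[2],
                x$predicted_tm))
  }
  invisible(x)
}

#' Write the thermometer annotation as BED
#'
#' Converts the internal 1-based inclusive interval to BED's 0-based
#' half-open convention (`start - 1`, `end`).
#'
#' @param record a `synthetic_record` with an annotation.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(record, path) {
  stopifnot(inherits(record, "synthetic_record"))
  if (is.null(record$thermometer_interval))
    stop("control records carry no thermometer annotation")
  line <- sprintf("%s\t%d\t%d\tthermometer", record$sequence$id,
                  record$thermometer_interval[1] - 1L,
                  record$thermometer_interval[2])
  writeLines(line, path)
  invisible(path)
}
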