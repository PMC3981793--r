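# The core scan: slide windows of every size in the requested range over
# the sequence one nucleotide at a time, fold each window at both
# temperatures, record the base-pair distance as a dot, and normalize
# intensities by the largest distance in the run.

#' Configuration of a two-temperature sliding-window scan
#'
#' Defaults follow the recommended working configuration for thermometer
#' scans: windows 55-80 nt, reference temperature 37 C, shock temperature
#' 40 C, MFE structures, builtin engine.  A minimum window below 50 or a
#' maximum above 150 makes energy-minimization predictions less reliable
#' and triggers a warning (not an error).
#'
#' @param t1 reference temperature, degrees C.
#' @param t2 shock temperature, degrees C.
#' @param wmin,wmax smallest and largest window size, nucleotides.
#' @param mode `"mfe"` or `"centroid"`.
#' @param engine engine name (see [register_engine()]).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(t1 = 37, t2 = 40, wmin = 55, wmax = 80,
                        mode = c("mfe", "centroid"), engine = "builtin") {
  mode <- match.arg(mode)
  t1 <- as_temperature(t1)
  t2 <- as_temperature(t2)
  if (!is.numeric(wmin) || !is.numeric(wmax) || wmin != round(wmin) ||
      wmax != round(wmax) || wmin < 1)
    stop("window sizes must be positive integers")
  if (wmin > wmax) stop("`wmin` must not exceed `wmax`")
  if (wmin < 50 || wmax > 150)
    warning("window sizes below 50 or above 150 nt can make energy-minimization predictions less reliable",
            call. = FALSE)
  structure(
    list(t1 = t1, t2 = t2, wmin = as.integer(wmin), wmax = as.integer(wmax),
         mode = mode, engine = engine),
    class = "scan_config"
  )
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf("<scan_config> %g C vs %g C, windows %d-%d, mode %s, engine %s\n",
              x$t1$celsius, x$t2$celsius, x$wmin, x$wmax, x$mode, x$engine))
  invisible(x)
}

#' Assign dot intensities proportional to distance
#'
#' `intensity = distance / max_distance` when any distance is nonzero
#' (largest distance maps to 1, i.e. black; zero distance to 0, i.e.
#' invisible); all zero when `max_distance` is 0.
#'
#' @param dots data frame with a `distance` column.
#' @param max_distance the maximum distance of the scan.
#' @return `dots` with an `intensity` column in `[0, 1]`.
#' @export
normalize_intensities <- function(dots, max_distance) {
  dots$intensity <- if (max_distance > 0) dots$distance / max_distance else
    rep(0, nrow(dots))
  dots
}

#' Run a two-temperature sliding-window scan
#'
#' For every window size `w` in `[wmin, wmax]` and every start `s` in
#' `[1, L - w + 1]`, the subsequence is folded at both temperatures under
#' the configured mode and the base-pair distance between the two
#' structures becomes one dot at `x = s` (left-most window position),
#' `y = s + w - 1` (right-most).  Dots are ordered by ascending window
#' size, then ascending start, and intensities are normalized by the
#' scan-wide maximum distance.
#'
#' @param seq an [rna_sequence].
#' @param config a [scan_config()].
#' @param params an `energy_params` object (builtin engine only).
#' @param clamp_window if the sequence is shorter than `wmin`, replace the
#'   window range by the single window `L` instead of failing.
#' @return An object of class `scan_result` with fields `sequence_id`,
#'   `sequence_length`, `config`, `dots` (data frame `x`, `y`, `window`,
#'   `distance`, `intensity`) and `max_distance`.
#' @export
run_scan <- function(seq, config = scan_config(), params = default_energy_params(),
                     clamp_window = FALSE) {
  stopifnot(inherits(seq, "rna_sequence"), inherits(config, "scan_config"))
  L <- seq$length
  wmin <- config$wmin
  wmax <- config$wmax
  if (L < wmin) {
    if (!clamp_window)
      stop(sprintf(
        "sequence '%s' (%d nt) is shorter than the minimum window (%d nt); use clamp_window = TRUE (--clamp-window) to scan the single window of size %d",
        seq$id, L, wmin, L
      ))
    wmin <- wmax <- L
  }
  if (config$t1$celsius == config$t2$celsius)
    warning("t1 equals t2: every distance (and intensity) will be zero",
            call. = FALSE)

  if (identical(config$engine, "builtin")) {
    raw <- scan_cpp(.base_codes(seq$residues), wmin, wmax,
                    config$t1$kelvin, config$t2$kelvin,
                    if (config$mode == "mfe") 0L else 1L,
                    .cpp_params(params))
    dots <- data.frame(x = raw$x, y = raw$x + raw$w - 1L, window = raw$w,
                       distance = raw$distance)
  } else {
    rows <- vector("list", sum(pmax(0L, L - wmin:wmax + 1L)))
    k <- 0L
    for (w in wmin:wmax) {
      if (L - w + 1L < 1L) next
      for (s in seq_len(L - w + 1L)) {
        sub <- rna_sequence(seq$id, substr(seq$residues, s, s + w - 1L))
        f1 <- fold(sub, config$t1, config$mode, config$engine, params)
        f2 <- fold(sub, config$t2, config$mode, config$engine, params)
        k <- k + 1L
        rows[[k]] <- c(s, s + w - 1L, w, bp_distance(f1$structure, f2$structure))
      }
    }
    m <- do.call(rbind, rows[seq_len(k)])
    dots <- data.frame(x = m[, 1], y = m[, 2], window = m[, 3], distance = m[, 4])
  }
  max_distance <- if (nrow(dots)) max(dots$distance) else 0L
  dots <- normalize_intensities(dots, max_distance)
  structure(
    list(sequence_id = seq$id, sequence_length = L, config = config,
         dots = dots, max_distance = as.integer(max_distance)),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %s (%d nt): %d dots, windows %d-%d at %g/%g C (%s), max distance %d\n",
              x$sequence_id, x$sequence_length, nrow(x$dots),
              x$config$wmin, x$config$wmax,
              x$config$t1$celsius, x$config$t2$celsius, x$config$mode,
              x$max_distance))
  invisible(x)
}

#' Per-position intensity profile of a scan
#'
#' `profile[p]` is the mean intensity over all dots whose window covers
#' position `p` (0 where no window covers `p`).  This condenses the dot
#' plot into a one-dimensional summary whose peaks sit over
#' temperature-sensitive segments; it is an aid for reading the plot, not
#' a significance measure.
#'
#' @param result a `scan_result`.
#' @return Numeric vector of length `sequence_length`.
#' @export
position_profile <- function(result) {
  stopifnot(inherits(result, "scan_result"))
  L <- result$sequence_length
  acc <- numeric(L + 1L)
  cnt <- numeric(L + 1L)
  d <- result$dots
  for (r in seq_len(nrow(d))) {
    acc[d$x[r]] <- acc[d$x[r]] + d$intensity[r]
    acc[d$y[r] + 1L] <- acc[d$y[r] + 1L] - d$intensity[r]
    cnt[d$x[r]] <- cnt[d$x[r]] + 1
    cnt[d$y[r] + 1L] <- cnt[d$y[r] + 1L] - 1
  }
  sums <- cumsum(acc)[seq_len(L)]
  counts <- cumsum(cnt)[seq_len(L)]
  ifelse(counts > 0, sums / pmax(counts, 1), 0)
}

#' Write scan dots as TSV
#'
#' Deterministic tab-separated output, one row per dot in scan order
#' (ascending window size, then start), header
#' `x  y  window  distance  intensity`; coordinates are 1-based inclusive.
#'
#' @param result a `scan_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(result, path) {
  stopifnot(inherits(result, "scan_result"))
  write.table(result$dots[, c("x", "y", "window", "distance", "intensity")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-position profile as TSV
#'
#' @inheritParams write_scan_tsv
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(result, path) {
  stopifnot(inherits(result, "scan_result"))
  prof <- position_profile(result)
  write.table(data.frame(position = seq_along(prof), profile = prof),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
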