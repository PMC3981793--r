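# Temperature-dependent free energies for the reduced nearest-neighbor model.
#
# Stacks carry both enthalpy and entropy, dG(T) = dH - T*dS, so helices
# genuinely melt as temperature rises.  Loops are purely entropic and are
# rescaled linearly with absolute temperature from their tabulated 37 C
# value.  No terminal-AU penalty, dangles, tetraloop bonuses or multibranch
# penalty: this keeps the dynamic program and the brute-force enumeration
# oracle provably equivalent.

#' @rdname energy_constants
#' @format NULL
#' @export
GAS_CONSTANT <- 1.98717e-3 # kcal/(mol*K)

#' Physical constants of the energy model
#'
#' `GAS_CONSTANT` is the molar gas constant in kcal/(mol K);
#' `PAIR_TYPES` lists the six canonical (wobble-inclusive) base-pair types
#' in the fixed order used throughout the package.
#'
#' @name energy_constants
#' @export
PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")

.T37 <- 310.15

#' Temperature in degrees Celsius and Kelvin
#'
#' @param celsius temperature in degrees Celsius.
#' @return An object of class `rna_temperature` with fields `celsius` and
#'   `kelvin`.
#' @examples
#' temperature(37)$kelvin # 310.15
#' @export
temperature <- function(celsius) {
  if (!is.numeric(celsius) || length(celsius) != 1L || !is.finite(celsius))
    stop("`celsius` must be a single finite number")
  kelvin <- celsius + 273.15
  if (kelvin <= 0) stop("temperature below absolute zero")
  structure(list(celsius = celsius, kelvin = kelvin), class = "rna_temperature")
}

as_temperature <- function(t) {
  if (inherits(t, "rna_temperature")) t else temperature(t)
}

#' Read a nearest-neighbor parameter file
#'
#' The file is tab-separated with sections `[STACK]` (context, dH, dS),
#' `[HAIRPIN]` (loop size, dG37) and `[LOOP]` (internal/bulge total
#' unpaired count, dG37); `#` starts a comment.  A comment of the form
#' `# version=<id>` names the parameter set.
#'
#' @param path path to the parameter file; the default is the set shipped
#'   with the package.
#' @return An object of class `energy_params` with fields `stack_dH`,
#'   `stack_dS` (6 x 6 matrices over [PAIR_TYPES], rows = outer pair,
#'   columns = inner pair), `hairpin_dG37`, `loop_dG37` (named numeric
#'   vectors by size) and `version`.
#' @export
read_energy_params <- function(path = system.file("extdata", "energy_params_v1.tsv",
                                                  package = "thermoscan")) {
  if (!file.exists(path)) stop(sprintf("parameter file not found: %s", path))
  lines <- readLines(path)
  version <- "unversioned"
  vm <- grep("^#\\s*version=", lines, value = TRUE)
  if (length(vm)) version <- sub("^#\\s*version=", "", vm[1])
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]

  section <- NA_character_
  stack_dH <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  stack_dS <- stack_dH
  hairpin <- numeric(0)
  loop <- numeric(0)
  for (ln in lines) {
    if (startsWith(ln, "[")) {
      section <- ln
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (identical(section, "[STACK]")) {
      ctx <- strsplit(f[1], "/", fixed = TRUE)[[1]]
      if (length(ctx) != 2 || !all(ctx %in% PAIR_TYPES))
        stop(sprintf("bad stacking context '%s' in %s", f[1], path))
      stack_dH[ctx[1], ctx[2]] <- as.numeric(f[2])
      stack_dS[ctx[1], ctx[2]] <- as.numeric(f[3])
    } else if (identical(section, "[HAIRPIN]")) {
      hairpin[f[1]] <- as.numeric(f[2])
    } else if (identical(section, "[LOOP]")) {
      loop[f[1]] <- as.numeric(f[2])
    } else {
      stop(sprintf("data line outside a section in %s: %s", path, ln))
    }
  }
  if (anyNA(stack_dH) || anyNA(stack_dS))
    stop("parameter file is missing stacking contexts")
  if (!all(as.character(3:30) %in% names(hairpin)))
    stop("parameter file must tabulate hairpin loops for sizes 3..30")
  if (!all(as.character(1:30) %in% names(loop)))
    stop("parameter file must tabulate internal/bulge loops for sizes 1..30")
  if (any(hairpin < 0) || any(loop < 0))
    stop("loop free energies must be nonnegative (loops are destabilizing)")
  structure(
    list(stack_dH = stack_dH, stack_dS = stack_dS,
         hairpin_dG37 = hairpin[as.character(3:30)],
         loop_dG37 = loop[as.character(1:30)],
         version = version),
    class = "energy_params"
  )
}

#' Default shipped parameter set (cached)
#'
#' @return The [read_energy_params()] result for the parameter file shipped
#'   with the package.
#' @export
default_energy_params <- function() {
  if (is.null(.thermoscan_env$default_params))
    .thermoscan_env$default_params <- read_energy_params()
  .thermoscan_env$default_params
}

#' @export
print.energy_params <- function(x, ...) {
  cat(sprintf("<energy_params> version %s: %d stacking contexts, hairpin sizes %s..%s, loop sizes %s..%s\n",
              x$version, sum(!is.na(x$stack_dH)),
              names(x$hairpin_dG37)[1], tail(names(x$hairpin_dG37), 1),
              names(x$loop_dG37)[1], tail(names(x$loop_dG37), 1)))
  invisible(x)
}

#' Free energy of a stacked pair at a given temperature
#'
#' `dG(T) = dH - T_kelvin * dS` for the ordered stacking context
#' `"<outer>/<inner>"`, e.g. `"CG/GC"` for a C-G pair stacked on an inner
#' G-C pair.
#'
#' @param ctx stacking context string, `"XY/ZW"` with both halves in
#'   [PAIR_TYPES].
#' @param t temperature in degrees C (or a [temperature()] object).
#' @param params an `energy_params` object.
#' @return Free energy in kcal/mol.
#' @export
stack_energy <- function(ctx, t, params = default_energy_params()) {
  t <- as_temperature(t)
  parts <- strsplit(ctx, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% PAIR_TYPES))
    stop(sprintf("unknown stacking context '%s'", ctx))
  params$stack_dH[parts[1], parts[2]] - t$kelvin * params$stack_dS[parts[1], parts[2]]
}

#' Free energy of a hairpin or internal/bulge loop
#'
#' Loops are purely entropic: `dG(T) = (T_kelvin / 310.15) * dG37(size)`.
#' Beyond the tabulated sizes a Jacobson-Stockmayer term extrapolates:
#' `dG37(s) = dG37(s_max) + 1.75 * R * 310.15 * ln(s / s_max)`.
#'
#' @param kind `"hairpin"` or `"internal"` (internal covers bulges; the
#'   size is the total unpaired count on both sides).
#' @param size unpaired nucleotide count (>= 3 for hairpins, >= 1 for
#'   internal/bulge loops).
#' @inheritParams stack_energy
#' @return Free energy in kcal/mol.
#' @export
loop_energy <- function(kind = c("hairpin", "internal"), size, t,
                        params = default_energy_params()) {
  kind <- match.arg(kind)
  t <- as_temperature(t)
  if (!is.numeric(size) || length(size) != 1L || size != round(size))
    stop("`size` must be a single integer")
  tab <- if (kind == "hairpin") params$hairpin_dG37 else params$loop_dG37
  smin <- as.integer(names(tab)[1])
  smax <- as.integer(tail(names(tab), 1))
  if (size < smin) {
    if (kind == "hairpin")
      stop(sprintf("hairpin loops need at least %d unpaired bases (got %d)", smin, size))
    stop(sprintf("internal/bulge loops need at least %d unpaired base (got %d)", smin, size))
  }
  g37 <- if (size <= smax) {
    unname(tab[as.character(size)])
  } else {
    unname(tab[as.character(smax)]) +
      1.75 * GAS_CONSTANT * .T37 * log(size / smax)
  }
  (t$kelvin / .T37) * g37
}

# parameter layout handed to the compiled engine
.cpp_params <- function(params) {
  hp <- numeric(30)
  hp[3:30] <- unname(params$hairpin_dG37[as.character(3:30)])
  lp <- unname(params$loop_dG37[as.character(1:30)])
  list(dH = unname(params$stack_dH), dS = unname(params$stack_dS),
       hp = hp, lp = lp)
}

# residue string -> 0-based base codes (A=0, C=1, G=2, U=3)
.base_codes <- function(residues) {
  m <- match(strsplit(residues, "", fixed = TRUE)[[1]], c("A", "C", "G", "U"))
  if (anyNA(m)) stop("sequence contains characters outside A/C/G/U")
  m - 1L
}

#' @importFrom utils tail
NULL
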