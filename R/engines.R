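# External folding engine adapters.  An engine is a function
# (residues, celsius, mode) -> list(dotbracket =, energy =); any engine
# satisfying the contract can be registered by name and used by fold() and
# run_scan().  The builtin engine is registered at load time.

#' Register a folding engine adapter
#'
#' @param name engine name.
#' @param fun adapter function `(residues, celsius, mode)` returning
#'   `list(dotbracket =, energy =)`; ignored for the reserved name
#'   `"builtin"`.
#' @return `name`, invisibly.
#' @export
register_engine <- function(name, fun) {
  if (is.null(.thermoscan_env$engines))
    .thermoscan_env$engines <- new.env(parent = emptyenv())
  if (!identical(name, "builtin") && !is.function(fun))
    stop("`fun` must be a function(residues, celsius, mode)")
  assign(name, fun, envir = .thermoscan_env$engines)
  invisible(name)
}

#' @rdname register_engine
#' @export
list_engines <- function() {
  if (is.null(.thermoscan_env$engines)) return(character(0))
  sort(ls(.thermoscan_env$engines))
}

get_engine <- function(name) {
  if (is.null(.thermoscan_env$engines) ||
      !exists(name, envir = .thermoscan_env$engines, inherits = FALSE))
    stop(sprintf("engine '%s' is not registered (available: %s)",
                 name, paste(list_engines(), collapse = ", ")))
  get(name, envir = .thermoscan_env$engines, inherits = FALSE)
}

#' Adapter for ViennaRNA's RNAfold
#'
#' Builds an engine adapter around an `RNAfold` binary, which folds with
#' the full Turner parameter set.  `mode = "mfe"` parses the MFE line;
#' `mode = "centroid"` runs with `-p` and parses the centroid line.
#' Additional command-line options (e.g. `--noLP`, `-d2`) are passed
#' through unchanged, with no claimed default.
#'
#' @param rnafold path to the RNAfold executable.
#' @param options character vector of extra RNAfold options.
#' @return An engine function suitable for [register_engine()].
#' @export
rnafold_engine <- function(rnafold = Sys.which("RNAfold"), options = character()) {
  rnafold <- as.character(rnafold)
  if (!nzchar(rnafold) || !file.exists(rnafold))
    stop("RNAfold binary not found; install ViennaRNA or pass its path")
  force(options)
  function(residues, celsius, mode) {
    dir <- tempfile("rnafold")
    dir.create(dir)
    old <- setwd(dir)
    on.exit({ setwd(old); unlink(dir, recursive = TRUE) }, add = TRUE)
    args <- c("--noPS", "-T", format(celsius), options)
    if (mode == "centroid") args <- c(args, "-p")
    out <- suppressWarnings(system2(rnafold, args,
                                    input = paste0(">q\n", residues),
                                    stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0)
      stop(sprintf("RNAfold exited with status %d; raw output: %s",
                   status, paste(out, collapse = " | ")))
    pat <- if (mode == "mfe") {
      "^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$"
    } else {
      "^([.()]+)\\s+\\{\\s*(-?[0-9.]+)"
    }
    hit <- grep(pat, out, value = TRUE)
    if (!length(hit))
      stop(sprintf("could not find a %s structure line; raw output: %s",
                   mode, paste(out, collapse = " | ")))
    m <- regmatches(hit[1], regexec(pat, hit[1]))[[1]]
    list(dotbracket = m[2], energy = as.numeric(m[3]))
  }
}
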