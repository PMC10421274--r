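# Bridge to the bundled RDKit helper (inst/python/molgraph.py).
#
# All structure perception and 3D embedding goes through one batched
# JSON-over-stdin call per request; results are memoised for the session so
# repeated featurization of the same SMILES (e.g. across a threshold sweep,
# which reuses the same conformer) costs one subprocess call.

.mathqsar_cache <- new.env(parent = emptyenv())

.python_bin <- function() {
  bin <- Sys.getenv("MATHQSAR_PYTHON", "")
  if (!nzchar(bin)) bin <- Sys.which("python")
  if (!nzchar(bin)) {
    stop("mathqsar requires a Python interpreter with rdkit on the PATH ",
         "(or set MATHQSAR_PYTHON)", call. = FALSE)
  }
  bin
}

.helper_script <- function() {
  path <- system.file("python", "molgraph.py", package = "mathqsar")
  if (!nzchar(path)) stop("bundled molgraph.py helper not found", call. = FALSE)
  path
}

# Run the helper for the subset of `smiles` not already cached under `mode`
# (+ seed/max_attempts for embed); returns the list of per-molecule records
# in input order.
.mol_query <- function(mode, smiles, seed = 42L, max_attempts = 5L) {
  stopifnot(mode %in% c("parse", "embed", "canon"), is.character(smiles))
  keys <- if (mode == "embed") {
    paste(mode, seed, max_attempts, smiles, sep = "\r")
  } else {
    paste(mode, smiles, sep = "\r")
  }
  missing_idx <- which(!vapply(keys, exists, logical(1),
                               envir = .mathqsar_cache))
  if (length(missing_idx)) {
    req <- list(mode = mode,
                smiles = as.list(smiles[missing_idx]),
                seed = as.integer(seed),
                max_attempts = as.integer(max_attempts))
    out <- suppressWarnings(system2(
      .python_bin(), shQuote(.helper_script()),
      input = jsonlite::toJSON(req, auto_unbox = TRUE, digits = NA),
      stdout = TRUE, stderr = FALSE))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0) {
      stop("RDKit helper failed (exit status ", status, ")", call. = FALSE)
    }
    recs <- jsonlite::fromJSON(paste(out, collapse = "\n"),
                               simplifyVector = FALSE)
    for (i in seq_along(missing_idx)) {
      assign(keys[missing_idx[i]], recs[[i]], envir = .mathqsar_cache)
    }
  }
  lapply(keys, get, envir = .mathqsar_cache)
}

#' Clear the session cache of parsed/embedded molecules
#'
#' Parsing and conformer-embedding results are memoised per session; call
#' this to force fresh subprocess calls (mainly useful in tests).
#'
#' @return Invisibly, the number of cache entries removed.
#' @export
clear_molecule_cache <- function() {
  n <- length(ls(.mathqsar_cache))
  rm(list = ls(.mathqsar_cache), envir = .mathqsar_cache)
  invisible(n)
}

.raise <- function(class, msg) {
  stop(structure(class = c(class, "mathqsar_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.check_record <- function(rec, smiles) {
  if (isTRUE(rec$ok)) return(invisible(rec))
  cls <- switch(rec$error_type %||% "parse",
                parse = "math_parse_error",
                sanitize = "math_sanitize_error",
                embed = "math_embed_error",
                "math_parse_error")
  .raise(cls, paste0(rec$error %||% "molecule processing failed",
                     " [", smiles, "]"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
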