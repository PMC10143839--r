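# Batched subprocess bridge to RDKit. All cheminformatics primitives
# (canonical SMILES, Morgan fingerprints, MOE-type descriptor values) go
# through inst/python/rdkit_tools.py; one process per table, never per
# molecule. Results are memoised per (input, parameters) in a package-local
# cache so repeated featurization of the same molecules is free.

.dfikit_cache <- new.env(parent = emptyenv())

.rdkit_python <- function() {
  p <- getOption("dfikit.python")
  if (!is.null(p)) return(p)
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  unname(p)
}

.rdkit_script <- function() {
  system.file("python", "rdkit_tools.py", package = "dfikit")
}

#' Is the RDKit toolkit bridge usable?
#'
#' The package delegates SMILES canonicalization, fingerprints, and descriptor
#' computation to RDKit through the `python` interpreter (option
#' `dfikit.python` overrides the interpreter found on `PATH`).
#'
#' @return `TRUE` if a working interpreter with RDKit is found.
#' @export
rdkit_available <- function() {
  if (!is.null(.dfikit_cache$rdkit_ok)) return(.dfikit_cache$rdkit_ok)
  ok <- FALSE
  py <- .rdkit_python()
  if (nzchar(py) && nzchar(.rdkit_script())) {
    ok <- tryCatch(
      identical(canonicalize_smiles("C", strict = TRUE), "C"),
      error = function(e) FALSE
    )
  }
  .dfikit_cache$rdkit_ok <- ok
  ok
}

# Run one bridge subcommand over a two-column (id, smiles) frame.
.rdkit_call <- function(cmd, smiles, extra = character()) {
  py <- .rdkit_python()
  .assert(nzchar(py), "no python interpreter found; set options(dfikit.python=)")
  script <- .rdkit_script()
  .assert(nzchar(script), "rdkit_tools.py not found in the installed package")
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.csv(
    data.frame(id = seq_along(smiles), smiles = smiles),
    fin, row.names = FALSE, quote = TRUE
  )
  status <- system2(py, c(script, cmd, "--in", fin, "--out", fout, extra),
                    stdout = FALSE, stderr = FALSE)
  .assert(identical(status, 0L) && file.exists(fout),
          "RDKit bridge call '%s' failed (is rdkit importable by %s?)", cmd, py)
  utils::read.csv(fout, colClasses = "character", check.names = FALSE)
}

.memo_get <- function(store, keys) {
  env <- .dfikit_cache[[store]]
  if (is.null(env)) {
    env <- new.env(parent = emptyenv())
    .dfikit_cache[[store]] <- env
  }
  list(env = env, hit = vapply(keys, function(k) !is.null(env[[k]]), logical(1)))
}

#' Canonicalize SMILES strings
#'
#' Normalizes SMILES to the toolkit's canonical form so that equivalent
#' notations (e.g. `"CCO"` and `"OCC"`) compare equal. Deterministic and
#' idempotent. Salts and stereochemistry are left untouched.
#'
#' @param smiles character vector of SMILES strings.
#' @param strict if `TRUE` (default), an unparseable SMILES raises an error
#'   naming the offending string; if `FALSE` it yields `NA`.
#' @return Character vector of canonical SMILES (with `NA` for failures when
#'   `strict = FALSE`).
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("CCO", "OCC"))  # both "CCO"
#' }
#' @export
canonicalize_smiles <- function(smiles, strict = TRUE) {
  .assert(is.character(smiles), "smiles must be a character vector")
  if (length(smiles) == 0) return(character(0))
  keys <- paste0("c|", smiles)
  memo <- .memo_get("canonical", keys)
  todo <- which(!memo$hit & !is.na(smiles))
  if (length(todo)) {
    res <- .rdkit_call("canonical", smiles[todo])
    for (i in seq_along(todo)) {
      v <- res$canonical_smiles[[i]]
      memo$env[[keys[todo[i]]]] <- if (nzchar(v)) v else NA_character_
    }
  }
  out <- vapply(keys, function(k) memo$env[[k]] %||% NA_character_,
                character(1), USE.NAMES = FALSE)
  out[is.na(smiles)] <- NA_character_
  if (strict && anyNA(out)) {
    bad <- smiles[is.na(out)]
    .stopf("invalid SMILES: %s", paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}

#' Morgan fingerprints for SMILES strings
#'
#' Circular (Morgan/ECFP-style) hashed fingerprints, the standard input for
#' Tanimoto structural similarity. Defaults (radius 2, 2048 bits) are the
#' ECFP4-equivalent convention.
#'
#' @param smiles character vector of valid SMILES.
#' @param radius Morgan radius (default 2).
#' @param n_bits fingerprint length (default 2048).
#' @return A [fingerprint_set]: logical matrix (molecules x bits) with
#'   attribute `params`.
#' @export
smiles_fingerprints <- function(smiles, radius = 2, n_bits = 2048) {
  .assert(is.character(smiles), "smiles must be a character vector")
  .assert(n_bits > 0, "n_bits must be positive")
  key <- function(s) sprintf("f|%d|%d|%s", radius, n_bits, s)
  keys <- vapply(smiles, key, character(1), USE.NAMES = FALSE)
  memo <- .memo_get("fingerprint", keys)
  todo <- which(!memo$hit)
  if (length(todo)) {
    res <- .rdkit_call("fp", smiles[todo],
                       c("--radius", radius, "--nbits", n_bits))
    for (i in seq_along(todo)) {
      if (nzchar(res$error[[i]])) .stopf("%s", res$error[[i]])
      on <- res$onbits[[i]]
      idx <- if (nzchar(on)) as.integer(strsplit(on, " ")[[1]]) + 1L else integer(0)
      memo$env[[keys[todo[i]]]] <- idx
    }
  }
  m <- matrix(FALSE, nrow = length(smiles), ncol = n_bits)
  for (i in seq_along(keys)) m[i, memo$env[[keys[i]]]] <- TRUE
  fingerprint_set(m, radius = radius)
}

#' Construct a fingerprint set
#'
#' Wraps a logical molecules-by-bits matrix with its generating parameters.
#' Used by [smiles_fingerprints()] and directly constructible for testing
#' with synthetic bit patterns.
#'
#' @param bits logical matrix, one row per molecule.
#' @param type,radius fingerprint parameter record.
#' @return Object of class `fingerprint_set`.
#' @export
fingerprint_set <- function(bits, type = "morgan", radius = 2) {
  .assert(is.matrix(bits) && is.logical(bits), "bits must be a logical matrix")
  .assert(ncol(bits) > 0, "fingerprint length must be positive")
  structure(bits,
            params = list(type = type, radius = radius, n_bits = ncol(bits)),
            class = c("fingerprint_set", "matrix", "array"))
}

#' @method print fingerprint_set
#' @export
print.fingerprint_set <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<fingerprint_set> %d molecules x %d bits (%s, radius %d)\n",
              nrow(x), p$n_bits, p$type, p$radius))
  invisible(x)
}
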