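#' Construct a compound set
#'
#' A compound set is an ordered table of molecules of one kind (`"drug"` or
#' `"food"`). Order is preserved because downstream similarity filtering is
#' order-sensitive (the first member of a redundant group is the one kept).
#'
#' @param id,name,smiles character vectors of equal length.
#' @param kind `"drug"` or `"food"`.
#' @param canonical_smiles optional pre-computed canonical form (`NA` where
#'   not yet computed or invalid).
#' @param origin_class optional `"organic"`/`"inorganic"`/`"unknown"`
#'   metadata; carried through but never used in computation.
#' @param provenance free-text source note (e.g. file path and toolkit
#'   version).
#' @return A tibble of class `compound_set` with columns
#'   `id, name, smiles, canonical_smiles, kind, origin_class`.
#' @export
compound_set <- function(id, name, smiles, kind = c("drug", "food"),
                         canonical_smiles = NA_character_,
                         origin_class = "unknown", provenance = "") {
  kind <- match.arg(kind)
  .assert(!anyDuplicated(id), "compound ids must be unique within a set")
  x <- tibble::tibble(
    id = as.character(id), name = as.character(name),
    smiles = as.character(smiles),
    canonical_smiles = rep_len(as.character(canonical_smiles), length(id)),
    kind = kind,
    origin_class = rep_len(as.character(origin_class), length(id))
  )
  attr(x, "provenance") <- provenance
  class(x) <- c("compound_set", class(x))
  x
}

#' Read a compound table from CSV/TSV
#'
#' One compound per row with a non-empty SMILES cell; rows whose SMILES cell
#' is empty or missing are dropped and counted (not raised) — the count is
#' folded into the ingest report by [drop_invalid_and_duplicates()].
#'
#' @param path file path; delimiter inferred from the extension (`.tsv` ->
#'   tab) unless `delim` is given.
#' @param kind `"drug"` or `"food"`.
#' @param id_col,name_col,smiles_col column names in the file.
#' @param delim field delimiter override.
#' @return A [compound_set] with attributes `n_input` and
#'   `n_missing_smiles`.
#' @export
read_compound_table <- function(path, kind = c("drug", "food"),
                                id_col = "id", name_col = "name",
                                smiles_col = "smiles", delim = NULL) {
  kind <- match.arg(kind)
  .assert(file.exists(path), "file not found: %s", path)
  delim <- delim %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.csv(path, sep = delim, colClasses = "character",
                         check.names = FALSE)
  for (col in c(id_col, smiles_col)) {
    .assert(col %in% names(raw), "column '%s' not found in %s", col, path)
  }
  nm <- if (name_col %in% names(raw)) raw[[name_col]] else raw[[id_col]]
  smi <- raw[[smiles_col]]
  keep <- !is.na(smi) & nzchar(trimws(smi))
  oc <- if ("origin_class" %in% names(raw)) raw$origin_class[keep] else "unknown"
  out <- compound_set(
    id = raw[[id_col]][keep], name = nm[keep], smiles = trimws(smi[keep]),
    kind = kind, origin_class = oc,
    provenance = sprintf("read_compound_table(%s)", path)
  )
  attr(out, "n_input") <- nrow(raw)
  attr(out, "n_missing_smiles") <- sum(!keep)
  out
}

#' Write a compound set to CSV
#'
#' @param x a [compound_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("id", "name", "smiles",
                                        "canonical_smiles", "kind",
                                        "origin_class")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Drop invalid and duplicate compounds
#'
#' Canonicalizes every SMILES, removes rows that fail to parse (counted, not
#' raised) and rows whose canonical SMILES was already seen (first occurrence
#' wins, preserving input order). The report partitions the input row count
#' exactly: `n_input = n_invalid_smiles + n_duplicates_removed + n_retained`,
#' where empty-SMILES rows dropped at read time count as invalid.
#'
#' @param x a [compound_set].
#' @return `list(compounds = <compound_set>, report = <ingest_report>)`.
#' @export
drop_invalid_and_duplicates <- function(x) {
  .assert(inherits(x, "compound_set"), "x must be a compound_set")
  n_missing <- attr(x, "n_missing_smiles") %||% 0L
  n_input <- attr(x, "n_input") %||% (nrow(x) + n_missing)
  can <- if (nrow(x)) canonicalize_smiles(x$smiles, strict = FALSE) else character(0)
  valid <- !is.na(can)
  dup <- valid & duplicated(can)
  keep <- valid & !dup
  out <- x[keep, , drop = FALSE]
  out$canonical_smiles <- can[keep]
  attr(out, "provenance") <- attr(x, "provenance")
  attr(out, "n_input") <- sum(keep)
  attr(out, "n_missing_smiles") <- 0L
  class(out) <- class(x)
  report <- ingest_report(
    n_input = n_input,
    n_invalid_smiles = n_missing + sum(!valid),
    n_duplicates_removed = sum(dup),
    n_retained = sum(keep)
  )
  list(compounds = out, report = report)
}

#' Ingest report
#'
#' Tallies how the rows of an input compound table were partitioned.
#'
#' @param n_input,n_invalid_smiles,n_duplicates_removed,n_retained
#'   nonnegative integer counts; must satisfy
#'   `n_input = n_invalid_smiles + n_duplicates_removed + n_retained`.
#' @return Object of class `ingest_report`.
#' @export
ingest_report <- function(n_input, n_invalid_smiles, n_duplicates_removed,
                          n_retained) {
  r <- list(n_input = as.integer(n_input),
            n_invalid_smiles = as.integer(n_invalid_smiles),
            n_duplicates_removed = as.integer(n_duplicates_removed),
            n_retained = as.integer(n_retained))
  .assert(all(unlist(r) >= 0), "ingest counts must be nonnegative")
  .assert(r$n_input == r$n_invalid_smiles + r$n_duplicates_removed + r$n_retained,
          "ingest report does not partition the input (%d != %d + %d + %d)",
          r$n_input, r$n_invalid_smiles, r$n_duplicates_removed, r$n_retained)
  structure(r, class = "ingest_report")
}

#' @method print ingest_report
#' @export
print.ingest_report <- function(x, ...) {
  cat(sprintf(
    "<ingest_report> %d rows in: %d invalid SMILES, %d duplicates removed, %d retained\n",
    x$n_input, x$n_invalid_smiles, x$n_duplicates_removed, x$n_retained))
  invisible(x)
}
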