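#' Tanimoto coefficient between two fingerprints
#'
#' `|A intersect B| / |A union B|` over on-bits. Symmetric, in `[0, 1]`.
#' Two all-zero fingerprints are defined as similarity 1 (identical
#' emptiness), so featureless molecules collapse to one representative; a
#' warning is emitted in that case.
#'
#' @param a,b logical vectors of equal length (fingerprint bit vectors).
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))  # 1/2
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  .assert(length(a) == length(b),
          "fingerprint lengths differ (%d vs %d)", length(a), length(b))
  un <- sum(a | b)
  if (un == 0) {
    .warnf("two all-zero fingerprints: similarity defined as 1")
    return(1)
  }
  sum(a & b) / un
}

# All-pairs Tanimoto via cross products on the 0/1 matrix.
.tanimoto_matrix <- function(bits) {
  m <- matrix(as.numeric(bits), nrow = nrow(bits))
  inter <- tcrossprod(m)
  pop <- rowSums(m)
  un <- outer(pop, pop, "+") - inter
  s <- inter / un
  s[un == 0] <- 1      # all-zero vs all-zero
  s
}

#' Greedy structural-redundancy filter
#'
#' Sweeps the compounds in set order: each compound that has not yet been
#' removed becomes a target and removes every later not-yet-removed query
#' whose Tanimoto similarity to it is `>=` the threshold. Targets are always
#' retained, and the sweep continues until the last compound. This is the
#' target/query deduplication used to thin structurally redundant food
#' constituents at threshold 0.75.
#'
#' @param compounds a [compound_set] (needs valid `canonical_smiles` or
#'   `smiles`), or `NULL` if `fingerprints` is given directly.
#' @param threshold rejection threshold in `(0, 1]` (default 0.75; a query
#'   with similarity greater than or equal to it is removed).
#' @param radius,n_bits Morgan fingerprint parameters.
#' @param fingerprints optional pre-computed [fingerprint_set]; rows must
#'   align with `ids`.
#' @param ids identifiers; defaults to `compounds$id` or row numbers.
#' @return A `similarity_filter_report`: list with `threshold`,
#'   `retained_ids` (ordered), and `removed` (tibble with columns
#'   `removed_id, matched_target_id, tanimoto`).
#' @export
greedy_dissimilarity_filter <- function(compounds = NULL, threshold = 0.75,
                                        radius = 2, n_bits = 2048,
                                        fingerprints = NULL, ids = NULL) {
  .assert(threshold > 0 && threshold <= 1, "threshold must be in (0, 1]")
  if (is.null(fingerprints)) {
    .assert(inherits(compounds, "compound_set"),
            "compounds must be a compound_set when fingerprints are not given")
    ids <- ids %||% compounds$id
    if (nrow(compounds) == 0) {
      return(structure(list(threshold = threshold, retained_ids = character(0),
                            removed = .empty_removed()),
                       class = "similarity_filter_report"))
    }
    smi <- ifelse(is.na(compounds$canonical_smiles), compounds$smiles,
                  compounds$canonical_smiles)
    fingerprints <- smiles_fingerprints(smi, radius = radius, n_bits = n_bits)
  }
  n <- nrow(fingerprints)
  ids <- as.character(ids %||% seq_len(n))
  .assert(length(ids) == n, "ids must match fingerprint rows")
  if (n == 0) {
    return(structure(list(threshold = threshold, retained_ids = character(0),
                          removed = .empty_removed()),
                     class = "similarity_filter_report"))
  }
  if (any(rowSums(fingerprints) == 0)) {
    .warnf("all-zero fingerprints present; they mutually count as similarity 1")
  }
  sim <- .tanimoto_matrix(fingerprints)
  alive <- rep(TRUE, n)
  rem_id <- character(0); rem_tgt <- character(0); rem_s <- numeric(0)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    if (i < n) {
      j <- which(alive & seq_len(n) > i & sim[i, ] >= threshold)
      if (length(j)) {
        alive[j] <- FALSE
        rem_id <- c(rem_id, ids[j])
        rem_tgt <- c(rem_tgt, rep(ids[i], length(j)))
        rem_s <- c(rem_s, sim[i, j])
      }
    }
  }
  structure(list(
    threshold = threshold,
    retained_ids = ids[alive],
    removed = tibble::tibble(removed_id = rem_id,
                             matched_target_id = rem_tgt,
                             tanimoto = rem_s)
  ), class = "similarity_filter_report")
}

.empty_removed <- function() {
  tibble::tibble(removed_id = character(0), matched_target_id = character(0),
                 tanimoto = numeric(0))
}

#' @method print similarity_filter_report
#' @export
print.similarity_filter_report <- function(x, ...) {
  cat(sprintf("<similarity_filter_report> threshold %.2f: %d retained, %d removed\n",
              x$threshold, length(x$retained_ids), nrow(x$removed)))
  invisible(x)
}

#' Apply a similarity filter report to a compound set
#'
#' @param compounds a [compound_set].
#' @param report a report from [greedy_dissimilarity_filter()].
#' @return The retained subset, order preserved.
#' @export
apply_similarity_filter <- function(compounds, report) {
  out <- compounds[compounds$id %in% report$retained_ids, , drop = FALSE]
  attr(out, "provenance") <- attr(compounds, "provenance")
  class(out) <- class(compounds)
  out
}
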