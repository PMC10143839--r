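#' The 3780-name pair-feature registry
#'
#' Expands the 60 per-molecule descriptor names into the pair feature space:
#' 120 singles (`drug.X`, `food.X`), 60 same-name sums (`X+X` meaning
#' `drug.X + food.X`), and 3600 ordered cross products (`X*Y` meaning
#' `drug.X * food.Y`). 120 + 60 + 3600 = 3780 names, fixed order.
#'
#' @param descriptors descriptor name vector (default
#'   [moe_descriptor_registry()]).
#' @return Character vector of 3780 feature names.
#' @export
pair_feature_registry <- function(descriptors = moe_descriptor_registry()) {
  k <- length(descriptors)
  c(paste0("drug.", descriptors),
    paste0("food.", descriptors),
    paste0(descriptors, "+", descriptors),
    paste0(rep(descriptors, each = k), "*", rep(descriptors, times = k)))
}

#' Resolve display feature names to registry names
#'
#' Reports in the field customarily print bare descriptor names (e.g.
#' `MRVSA0`) for single-molecule features; the registry stores them
#' role-prefixed. A bare descriptor name resolves to its `drug.`-prefixed
#' entry; sum and product names resolve as-is.
#'
#' @param names character vector of display or registry feature names.
#' @param descriptors descriptor registry in use.
#' @return Character vector of valid registry names; errors on any name
#'   that resolves to nothing.
#' @export
resolve_pair_feature <- function(names, descriptors = moe_descriptor_registry()) {
  reg <- pair_feature_registry(descriptors)
  out <- ifelse(names %in% reg, names,
                ifelse(names %in% descriptors, paste0("drug.", names), NA))
  if (anyNA(out)) {
    .stopf("unknown pair feature name(s): %s",
           paste(names[is.na(out)], collapse = ", "))
  }
  out
}

.check_desc_vector <- function(v, what) {
  reg <- moe_descriptor_registry()
  .assert(is.numeric(v) && !is.null(names(v)) && setequal(names(v), reg),
          "%s must be a named numeric vector over the 60-name registry", what)
  v[reg]
}

#' Featurize one drug-food pair
#'
#' Maps two 60-element descriptor vectors to the 3780-element pair feature
#' vector: the two copies of the singles, the 60 same-name sums, and the
#' 3600 ordered products.
#'
#' @param drug_desc,food_desc named numeric vectors over the descriptor
#'   registry.
#' @return Named numeric vector of length 3780 in registry order.
#' @export
featurize_pair <- function(drug_desc, food_desc) {
  d <- .check_desc_vector(drug_desc, "drug_desc")
  f <- .check_desc_vector(food_desc, "food_desc")
  # products ordered drug-index-major: d1*f1, d1*f2, ..., d60*f60
  out <- c(d, f, d + f, as.vector(t(outer(d, f))))
  names(out) <- pair_feature_registry()
  out
}

#' Featurize a table of labeled pairs
#'
#' Batch driver: looks up each pair's drug and food descriptor rows and
#' assembles the full feature table with vectorized matrix arithmetic.
#'
#' @param pairs tibble with columns `drug_id`, `food_id` and optionally
#'   `label`.
#' @param drug_descs,food_descs descriptor tables from
#'   [compute_moe_descriptors()] (column `id` + 60 descriptor columns).
#' @return A `pair_feature_table`: tibble with `drug_id`, `food_id`,
#'   `label` (NA if absent) and the 3780 feature columns in registry order.
#' @export
featurize_pairs <- function(pairs, drug_descs, food_descs) {
  reg <- moe_descriptor_registry()
  .assert(all(c("drug_id", "food_id") %in% names(pairs)),
          "pairs needs drug_id and food_id columns")
  for (tb in list(drug_descs, food_descs)) {
    .assert(all(c("id", reg) %in% names(tb)),
            "descriptor tables need an id column plus the 60 registry columns")
  }
  di <- match(as.character(pairs$drug_id), drug_descs$id)
  fi <- match(as.character(pairs$food_id), food_descs$id)
  if (anyNA(di)) .stopf("no descriptor row for drug id: %s",
                        pairs$drug_id[which(is.na(di))[1]])
  if (anyNA(fi)) .stopf("no descriptor row for food id: %s",
                        pairs$food_id[which(is.na(fi))[1]])
  k <- length(reg)
  D <- as.matrix(drug_descs[di, reg, drop = FALSE])
  F_ <- as.matrix(food_descs[fi, reg, drop = FALSE])
  X <- cbind(D, F_, D + F_,
             D[, rep(seq_len(k), each = k), drop = FALSE] *
               F_[, rep(seq_len(k), times = k), drop = FALSE])
  colnames(X) <- pair_feature_registry(reg)
  out <- tibble::as_tibble(X)
  out <- tibble::add_column(
    out,
    drug_id = as.character(pairs$drug_id),
    food_id = as.character(pairs$food_id),
    label = if ("label" %in% names(pairs)) as.integer(pairs$label) else NA_integer_,
    .before = 1
  )
  class(out) <- c("pair_feature_table", class(out))
  out
}

#' Extract the numeric feature matrix from a pair feature table
#'
#' @param table a `pair_feature_table` (or any frame containing the
#'   registry columns).
#' @return `list(X = numeric matrix, y = integer labels or NULL,
#'   ids = tibble(drug_id, food_id))`.
#' @export
pair_feature_matrix <- function(table) {
  reg <- pair_feature_registry()
  .assert(all(reg %in% names(table)), "table lacks registry feature columns")
  list(
    X = as.matrix(table[, reg, drop = FALSE]),
    y = if ("label" %in% names(table)) as.integer(table$label) else NULL,
    ids = tibble::tibble(drug_id = table$drug_id, food_id = table$food_id)
  )
}

#' Remove pairs with duplicate feature means
#'
#' Computes the arithmetic mean of each row's 3780 features (fixed column
#' order) and keeps only the first row within each group of equal means.
#' Equality is taken after rounding the mean to 12 significant digits to
#' guard against last-bit platform drift; idempotent. This excludes
#' effectively duplicated interacting pairs before splitting, so models are
#' not trained repeatedly on the same structure pattern.
#'
#' @param table a `pair_feature_table`.
#' @return `list(table = deduplicated table, n_removed = count)`.
#' @export
dedup_by_mean <- function(table) {
  reg <- pair_feature_registry()
  .assert(all(reg %in% names(table)), "table lacks registry feature columns")
  if (nrow(table) == 0) return(list(table = table, n_removed = 0L))
  m <- signif(rowMeans(as.matrix(table[, reg, drop = FALSE])), 12)
  dup <- duplicated(m)
  out <- table[!dup, , drop = FALSE]
  class(out) <- class(table)
  list(table = out, n_removed = sum(dup))
}
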