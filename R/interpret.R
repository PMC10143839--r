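#' Per-feature additive attribution of a boosted-tree model
#'
#' Exact TreeSHAP-style attributions for the gradient-boosted family: for
#' every sample, feature, and class, an additive contribution such that the
#' contributions plus the per-class base value reproduce the model's margin
#' output (local accuracy). Other families raise a capability error
#' (permutation importance is the alternative for non-additive-tree models).
#'
#' @param model a `dfi_model` with `family = "xgboost"`.
#' @param X feature matrix matching the model registry.
#' @return An `attribution_matrix`: list with `values` (array samples x
#'   features x classes), `base` (matrix samples x classes), and the
#'   feature/class registries.
#' @export
attribute_predictions <- function(model, X) {
  .assert(inherits(model, "dfi_model"), "model must be a dfi_model")
  if (model$family != "xgboost") {
    .stopf(paste("additive tree attribution requires the gradient-boosted",
                 "family; for '%s' use permutation importance instead"),
           model$family)
  }
  .assert(identical(colnames(X), model$feature_names),
          "feature registry mismatch between model and X")
  contrib <- predict(model$fit, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
  p <- length(model$feature_names)
  values <- contrib[, , seq_len(p), drop = FALSE]      # n x class x feature
  values <- aperm(values, c(1, 3, 2))                  # n x feature x class
  dimnames(values) <- list(NULL, model$feature_names,
                           as.character(model$classes))
  base <- contrib[, , p + 1]
  structure(list(values = values, base = matrix(base, nrow = nrow(X)),
                 feature_names = model$feature_names,
                 classes = model$classes),
            class = "attribution_matrix")
}

#' Ranked attribution summary with directions
#'
#' Ranks features by mean absolute attribution (averaged over samples, then
#' over classes) and records, per class, the direction of association
#' between feature value and attribution (sign of the Spearman
#' correlation). A constant feature or constant attribution yields an
#' undetermined (`NA`) direction.
#'
#' @param matrix an [attribute_predictions()] result.
#' @param X the feature matrix the attributions were computed on.
#' @return An `attribution_summary`: list with `ranking` (tibble `feature`,
#'   `mean_abs_attribution`, `rank`) and `directions` (features x classes
#'   matrix of -1/0/1/NA).
#' @export
summarize_attribution <- function(matrix, X) {
  .assert(inherits(matrix, "attribution_matrix"),
          "matrix must be an attribution_matrix")
  .assert(identical(colnames(X), matrix$feature_names),
          "X does not align with the attribution matrix")
  v <- matrix$values
  mean_abs <- apply(abs(v), c(2, 3), mean)             # feature x class
  agg <- rowMeans(mean_abs)
  ord <- order(-agg, seq_along(agg))                   # tie -> registry order
  ranking <- tibble::tibble(
    feature = matrix$feature_names[ord],
    mean_abs_attribution = agg[ord],
    rank = seq_along(ord)
  )
  dirs <- sapply(seq_along(matrix$classes), function(k) {
    vapply(seq_along(matrix$feature_names), function(j) {
      x <- X[, j]
      a <- v[, j, k]
      if (stats::sd(x) == 0 || stats::sd(a) == 0) return(NA_real_)
      sign(stats::cor(x, a, method = "spearman"))
    }, numeric(1))
  })
  dirs <- base::matrix(dirs, ncol = length(matrix$classes),
                       dimnames = list(matrix$feature_names,
                                       as.character(matrix$classes)))
  structure(list(ranking = ranking, directions = dirs),
            class = "attribution_summary")
}

#' @method print attribution_summary
#' @export
print.attribution_summary <- function(x, ...) {
  cat("<attribution_summary> top features by mean |attribution|:\n")
  print(utils::head(x$ranking, 10))
  invisible(x)
}
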