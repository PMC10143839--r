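.recommendation_templates <- c(
  `0` = "%s should not be taken with food containing %s",
  `1` = "%s could be taken with food containing %s",
  `2` = "%s may be taken with food containing %s"
)

#' Render a recommendation sentence for a drug-food pair
#'
#' Maps the predicted interaction class to its fixed clinical-style
#' sentence: positive (1) "could be taken with food containing", negative
#' (0) "should not be taken with food containing", non-significant (2)
#' "may be taken with food containing". Templates are byte-exact and in
#' bijection with the classes.
#'
#' @param drug_name,food_name non-empty display names.
#' @param label interaction class in `{0, 1, 2}`.
#' @return A `recommendation`: list with `drug_name`, `food_name`, `label`,
#'   `sentence`.
#' @examples
#' recommend_pair("Tetracycline", "Calcium", 0)$sentence
#' @export
recommend_pair <- function(drug_name, food_name, label) {
  .assert(nzchar(drug_name) && nzchar(food_name), "names must be non-empty")
  .assert(length(label) == 1 && label %in% 0:2,
          "label must be one of 0, 1, 2")
  sentence <- sprintf(.recommendation_templates[[as.character(label)]],
                      drug_name, food_name)
  structure(list(drug_name = drug_name, food_name = food_name,
                 label = as.integer(label), sentence = sentence),
            class = "recommendation")
}

#' @method print recommendation
#' @export
print.recommendation <- function(x, ...) {
  cat(x$sentence, "\n")
  invisible(x)
}

#' Predict and render recommendations for a batch of pairs
#'
#' Runs the model on the feature rows and renders one sentence per pair,
#' order preserved.
#'
#' @param model a `dfi_model`.
#' @param features numeric matrix matching the model registry, one row per
#'   pair.
#' @param drug_names,food_names display names aligned with the rows.
#' @return Tibble with `drug_name`, `food_name`, `label`, `sentence`.
#' @export
recommend_batch <- function(model, features, drug_names, food_names) {
  .assert(nrow(features) == length(drug_names) &&
            nrow(features) == length(food_names),
          "names must align with feature rows")
  if (nrow(features) == 0) {
    return(tibble::tibble(drug_name = character(0), food_name = character(0),
                          label = integer(0), sentence = character(0)))
  }
  labels <- predict(model, features)
  tibble::tibble(
    drug_name = as.character(drug_names),
    food_name = as.character(food_names),
    label = as.integer(labels),
    sentence = vapply(seq_along(labels), function(i) {
      recommend_pair(drug_names[i], food_names[i], labels[i])$sentence
    }, character(1))
  )
}
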