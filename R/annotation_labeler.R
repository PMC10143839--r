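#' Normalize annotation text
#'
#' Lowercases, collapses punctuation to spaces, collapses internal
#' whitespace, and trims. Idempotent; all phrase matching operates on this
#' normal form.
#'
#' @param text character vector.
#' @return Normalized character vector.
#' @export
normalize_text <- function(text) {
  x <- tolower(as.character(text))
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

#' Default labeling rule set for food-interaction annotations
#'
#' Trigger vocabulary for converting DrugBank-style free-text food
#' interaction sentences into three classes: negative (0), positive (1), and
#' non-significant (2), with an "ignored" bucket for purely administrative
#' sentences. Phrases are matched as normalized substrings (single words with
#' word boundaries); pharmacokinetic and adverse-effect patterns are small
#' keyword regexes over the normalized text.
#'
#' Classes:
#' * negative — explicit triggers ("avoid", "take separately from meals",
#'   "take on an empty stomach", "take before a meal", harm phrases), or a
#'   pharmacokinetic decrease (reduced absorption / bioavailability / peak
#'   concentration, or increased time to peak) together with an
#'   adverse-effect mention;
#' * positive — explicit triggers ("take with food", "take after meals" /
#'   "take after a meal", benefit phrases such as "reduce nausea"), or a
#'   pharmacokinetic increase with no adverse-effect mention;
#' * non-significant — "take with or without food", "take consistently with
#'   regard to food", and any sentence matching no rule at all;
#' * ignored — "take at the same time every day" when no other rule matches.
#'
#' @return A `label_rule_set` list; editable and re-usable in
#'   [classify_annotation()].
#' @export
default_label_rules <- function() {
  rules <- list(
    ignore_phrases = c("take at the same time every day"),
    negative_phrases = c(
      "avoid",
      "take separately from meals",
      "take on an empty stomach",
      "take before a meal",
      "causes harm", "cause harm to the patient", "harm to the patient"
    ),
    positive_phrases = c(
      "take with food",
      "take after meals", "take after a meal",
      "reduce nausea", "reduces nausea",
      "reduce irritation", "reduces irritation",
      "decreases the risk of gastrointestinal side effects",
      "reduce the risk of gastrointestinal side effects",
      "will benefit the patient"
    ),
    nonsignificant_phrases = c(
      "take with or without food",
      "take consistently with regard to food"
    ),
    pk_increase_patterns = c(
      "\\bincreas(e|es|ed|ing)\\b[a-z0-9 ]*\\b(absorption|bioavailability|peak concentration)",
      "\\b(decreas(e|es|ed|ing)|reduc(e|es|ed|ing))\\b[a-z0-9 ]*\\btime to peak"
    ),
    pk_decrease_patterns = c(
      "\\b(decreas(e|es|ed|ing)|reduc(e|es|ed|ing))\\b[a-z0-9 ]*\\b(absorption|bioavailability|peak concentration)",
      "\\bincreas(e|es|ed|ing)\\b[a-z0-9 ]*\\btime to peak"
    ),
    adverse_effect_patterns = c(
      "\\btoxic(ity)?\\b", "\\badverse\\b", "\\bharm(ful)?\\b",
      "\\brisk of (toxicity|bleeding|death|liver|kidney)"
    ),
    precedence = c("negative", "positive", "non_significant")
  )
  class(rules) <- "label_rule_set"
  rules
}

.phrase_hits <- function(norm, phrases) {
  hits <- vapply(phrases, function(p) {
    if (!grepl(" ", p)) grepl(paste0("\\b", p, "\\b"), norm) else grepl(p, norm, fixed = TRUE)
  }, logical(1))
  phrases[hits]
}

.pattern_hits <- function(norm, patterns) {
  patterns[vapply(patterns, grepl, logical(1), x = norm)]
}

# Negated adverse mentions ("no adverse effect or toxicity", "without
# toxicity") are part of the positive-class definition and must not count
# as adverse-effect evidence.
.scrub_negated_adverse <- function(norm) {
  gsub("\\b(no|without|not cause) (adverse( effects?)?( or toxicity)?|toxicity|harm)\\b",
       " ", norm)
}

#' Classify one annotation sentence
#'
#' Evaluates, in order: ignore phrases; explicit negative triggers;
#' pharmacokinetic-decrease plus adverse-effect conjunction (negative);
#' explicit positive triggers; pharmacokinetic-increase with no
#' adverse-effect mention (positive); non-significant triggers; and a
#' non-significant fallback for sentences matching nothing. A sentence whose
#' only match is an ignore phrase is "ignored". All matched rules are
#' recorded.
#'
#' @param text one annotation sentence.
#' @param rules a [default_label_rules()]-style rule set.
#' @return A `label_decision`: list with `label` (0, 1, 2, or `NA` for
#'   ignored), `status` (`"negative"`, `"positive"`, `"non_significant"`,
#'   `"ignored"`), and `matched_rules` (tibble `rule`, `pattern`).
#' @examples
#' classify_annotation("Take with food to reduce nausea.")$label   # 1
#' classify_annotation("Avoid alcohol.")$label                     # 0
#' classify_annotation("Take with or without food.")$label         # 2
#' @export
classify_annotation <- function(text, rules = default_label_rules()) {
  .assert(length(text) == 1, "classify_annotation takes one sentence")
  norm <- normalize_text(text)
  .assert(nzchar(norm), "annotation text is empty after normalization")

  m <- list(
    ignore = .phrase_hits(norm, rules$ignore_phrases),
    negative = .phrase_hits(norm, rules$negative_phrases),
    positive = .phrase_hits(norm, rules$positive_phrases),
    nonsig = .phrase_hits(norm, rules$nonsignificant_phrases),
    pk_increase = .pattern_hits(norm, rules$pk_increase_patterns),
    pk_decrease = .pattern_hits(norm, rules$pk_decrease_patterns),
    adverse = .pattern_hits(.scrub_negated_adverse(norm),
                            rules$adverse_effect_patterns)
  )
  matched <- tibble::tibble(
    rule = rep(names(m), lengths(m)),
    pattern = unlist(m, use.names = FALSE) %||% character(0)
  )

  has_adverse <- length(m$adverse) > 0
  status <-
    if (length(m$negative)) "negative"
    else if (length(m$pk_decrease) && has_adverse) "negative"
    else if (length(m$positive)) "positive"
    else if (length(m$pk_increase) && !has_adverse) "positive"
    else if (length(m$nonsig)) "non_significant"
    else if (length(m$ignore)) "ignored"
    else "non_significant"   # fallback: does not fall into the other classes

  label <- switch(status, negative = 0L, positive = 1L,
                  non_significant = 2L, ignored = NA_integer_)
  structure(list(label = label, status = status, matched_rules = matched,
                 source_texts = as.character(text)),
            class = "label_decision")
}

#' @method print label_decision
#' @export
print.label_decision <- function(x, ...) {
  cat(sprintf("<label_decision> %s (label %s); %d rule match(es)\n",
              x$status, ifelse(is.na(x$label), "-", x$label),
              nrow(x$matched_rules)))
  invisible(x)
}

#' Combine all annotations of one drug into a drug-level label
#'
#' Per-annotation decisions are combined under the precedence
#' negative > positive > non-significant (safety first). A drug whose every
#' annotation is ignored gets an ignored decision and contributes no pairs
#' downstream; if any annotation matches a real class, ignore-only sentences
#' do not mask it.
#'
#' @param texts character vector of annotation sentences for one drug.
#' @param rules rule set.
#' @return A `label_decision` for the drug.
#' @export
label_drug <- function(texts, rules = default_label_rules()) {
  .assert(length(texts) >= 1, "at least one annotation is required")
  decisions <- lapply(texts, classify_annotation, rules = rules)
  statuses <- vapply(decisions, `[[`, character(1), "status")
  status <- if (all(statuses == "ignored")) "ignored" else {
    pr <- rules$precedence %||% c("negative", "positive", "non_significant")
    pr[pr %in% statuses][1]
  }
  label <- switch(status, negative = 0L, positive = 1L,
                  non_significant = 2L, ignored = NA_integer_)
  structure(list(
    label = label, status = status,
    matched_rules = do.call(rbind, lapply(decisions, `[[`, "matched_rules")),
    source_texts = as.character(texts)
  ), class = "label_decision")
}

#' Label every drug in an annotation table
#'
#' @param annotations tibble/data.frame with columns `drug_id`, `text`.
#' @param rules rule set.
#' @return Tibble with one row per drug: `drug_id`, `label` (`NA` =
#'   ignored), `status`. Drug order follows first appearance.
#' @export
label_drugs <- function(annotations, rules = default_label_rules()) {
  .assert(all(c("drug_id", "text") %in% names(annotations)),
          "annotations need columns drug_id, text")
  ids <- unique(as.character(annotations$drug_id))
  rows <- lapply(ids, function(d) {
    dec <- label_drug(annotations$text[annotations$drug_id == d], rules)
    tibble::tibble(drug_id = d, label = dec$label, status = dec$status)
  })
  do.call(rbind, rows)
}

#' Broadcast drug-level labels to drug-food pairs
#'
#' Forms the Cartesian product of labeled drugs (ignored drugs excluded) and
#' food compounds; every pair inherits its drug's label. Ordering is
#' deterministic: drug order, then food order.
#'
#' @param drug_labels output of [label_drugs()] (columns `drug_id`,
#'   `label`).
#' @param foods a [compound_set] of food constituents (or any table with an
#'   `id` column).
#' @return Tibble of labeled pairs: `drug_id`, `food_id`, `label` in
#'   `{0, 1, 2}`.
#' @export
build_pairs <- function(drug_labels, foods) {
  .assert(all(c("drug_id", "label") %in% names(drug_labels)),
          "drug_labels needs columns drug_id, label")
  keep <- drug_labels[!is.na(drug_labels$label), , drop = FALSE]
  .assert(nrow(keep) > 0, "no drug carries a usable label (all ignored)")
  food_ids <- as.character(foods$id)
  .assert(length(food_ids) > 0, "foods is empty")
  tibble::tibble(
    drug_id = rep(keep$drug_id, each = length(food_ids)),
    food_id = rep(food_ids, times = nrow(keep)),
    label = rep(as.integer(keep$label), each = length(food_ids))
  )
}
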