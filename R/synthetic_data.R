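# Fragment pools for the synthetic SMILES grammar. Any concatenation of
# start + middle segments + tail is a valid SMILES by construction; the
# pools mix aliphatic/aromatic carbon, N/O/S heteroatoms, halogens, and
# acid/amide/nitrile groups so all seven descriptor families vary.
.frag_start <- c("C", "CC", "CCC", "CCCC", "CC(C)", "CCO", "CCN")
.frag_branch <- c("O", "N", "Cl", "F", "Br", "S", "C(=O)O", "C(=O)N",
                  "C#N", "CO", "[N+](=O)[O-]", "C(F)(F)F")
.frag_ring <- c("c1ccccc1", "c1ccc(O)cc1", "c1ccc(N)cc1", "c1ccc(Cl)cc1",
                "c1ccc(OC)cc1", "c1ccc(C(=O)O)cc1", "c1ccncc1", "c1ccco1",
                "c1cccs1", "c1ccc2ccccc2c1", "C1CCCCC1", "C1CCNCC1",
                "C1CCOCC1")
.frag_terminal <- c("", "O", "N", "C(=O)O", "C(=O)OC", "C#N", "S", "OC")

.random_smiles <- function() {
  k <- sample(0:4, 1)
  mid <- if (k > 0) {
    paste(vapply(seq_len(k), function(i) {
      if (runif(1) < 0.45) paste0("C(", sample(.frag_branch, 1), ")") else "C"
    }, character(1)), collapse = "")
  } else ""
  tail <- if (runif(1) < 0.55) sample(.frag_ring, 1) else sample(.frag_terminal, 1)
  paste0(sample(.frag_start, 1), mid, tail)
}

#' Generate a synthetic compound library
#'
#' Assembles `n` structurally distinct molecules from a fragment grammar
#' (alkyl chains, O/N/S/halogen substituents, aromatic and aliphatic rings,
#' acid/amide/nitrile terminals). Every generated SMILES is valid by
#' construction; distinctness is enforced on canonical SMILES. Deterministic
#' per seed.
#'
#' @param n number of molecules.
#' @param seed RNG seed.
#' @param kind `"drug"` or `"food"`.
#' @param prefix id prefix (defaults to `"DRG"`/`"FOOD"` by kind).
#' @return A [compound_set] of `n` compounds with canonical SMILES filled
#'   in.
#' @export
generate_compound_library <- function(n, seed = 42, kind = c("drug", "food"),
                                      prefix = NULL) {
  kind <- match.arg(kind)
  .assert(n >= 1, "n must be at least 1")
  prefix <- prefix %||% if (kind == "drug") "DRG" else "FOOD"
  smiles <- character(0)
  canon <- character(0)
  .with_seed(derive_seed(seed, paste0("library-", kind)), {
    attempts <- 0
    while (length(smiles) < n) {
      .assert(attempts < 200 * n, "fragment grammar failed to yield %d distinct molecules", n)
      batch <- unique(vapply(seq_len(max(16, n)), function(i) .random_smiles(),
                             character(1)))
      attempts <- attempts + length(batch)
      cb <- canonicalize_smiles(batch, strict = TRUE)
      new <- !(cb %in% canon) & !duplicated(cb)
      smiles <- c(smiles, batch[new])
      canon <- c(canon, cb[new])
    }
  })
  compound_set(
    id = sprintf("%s%04d", prefix, seq_len(n)),
    name = sprintf("%s compound %d", kind, seq_len(n)),
    smiles = smiles[seq_len(n)], kind = kind,
    canonical_smiles = canon[seq_len(n)],
    provenance = sprintf("generate_compound_library(n=%d, seed=%s)", n, seed)
  )
}

.annotation_lexicon <- list(
  negative = c(
    "Avoid alcohol.",
    "Avoid grapefruit juice.",
    "Take on an empty stomach.",
    "Take separately from meals.",
    "Take before a meal.",
    "Food reduces the absorption of this drug and increases the risk of toxicity."
  ),
  positive = c(
    "Take with food.",
    "Take after a meal.",
    "Take with food to reduce nausea.",
    "Food increases the bioavailability of this drug.",
    "Food reduces irritation.",
    "Take after meals."
  ),
  non_significant = c(
    "Take with or without food.",
    "Take consistently with regard to food.",
    "Food does not alter the plasma profile of this drug."
  ),
  ignore = c("Take at the same time every day.")
)

#' Generate annotation sentences with known class assignments
#'
#' Assigns each drug a ground-truth class according to the proportions
#' (largest-remainder rounding), then samples 1-3 sentences from that
#' class's trigger lexicon, occasionally adding an administrative ignore
#' sentence. The default mix 0.20 / 0.33 / 0.47
#' (negative / positive / non-significant) mirrors the class imbalance of
#' curated DFI annotation corpora.
#'
#' @param drugs a [compound_set] of drugs.
#' @param proportions length-3 vector (negative, positive,
#'   non-significant) summing to 1.
#' @param seed RNG seed.
#' @return `list(annotations = tibble(drug_id, text),
#'   truth = tibble(drug_id, label))`.
#' @export
generate_annotations <- function(drugs, proportions = c(0.20, 0.33, 0.47),
                                 seed = 42) {
  .assert(length(proportions) == 3 && all(proportions >= 0) &&
            abs(sum(proportions) - 1) < 1e-9,
          "proportions must be a 3-vector summing to 1")
  n <- nrow(drugs)
  base <- floor(proportions * n)
  extra <- order(proportions * n - base, decreasing = TRUE)
  add <- rep(0L, 3)
  if (n - sum(base) > 0) add[extra[seq_len(n - sum(base))]] <- 1L
  counts <- base + add
  labels <- rep(c(0L, 1L, 2L), counts)
  lex_of <- c(`0` = "negative", `1` = "positive", `2` = "non_significant")
  rows <- list()
  .with_seed(derive_seed(seed, "annotations"), {
    labels <- sample(labels)
    for (i in seq_len(n)) {
      lex <- .annotation_lexicon[[lex_of[[as.character(labels[i])]]]]
      k <- sample(1:min(3, length(lex)), 1)
      texts <- sample(lex, k)
      if (runif(1) < 0.2) texts <- c(texts, .annotation_lexicon$ignore)
      rows[[i]] <- tibble::tibble(drug_id = drugs$id[i], text = texts)
    }
  })
  list(annotations = do.call(rbind, rows),
       truth = tibble::tibble(drug_id = drugs$id, label = labels))
}

#' Synthetic study configuration
#'
#' Defaults define the package's reference synthetic study: 30 drugs by
#' 100 foods (3000 pairs), 2% label noise, seed 42, with the true class
#' driven by two planted pair features: the cross-molecule
#' electrotopological surface sum `VSAEstate9+VSAEstate9` and the drug-side
#' E-state surface bin `drug.EstateVSA8`. Planted features must be
#' identifiable: each one has to carry more label signal than any feature
#' correlated with it above the cascade's pruning threshold, otherwise no
#' selection procedure could be expected to recover it.
#'
#' @param n_drugs,n_foods library sizes.
#' @param seed master seed.
#' @param class_proportions annotation class mix (used by
#'   [generate_annotations()]).
#' @param label_noise fraction of planted labels flipped uniformly to
#'   another class, in `[0, 0.5]`.
#' @param planted_features pair-feature names driving the true label.
#' @param planted_weights linear score weights, one per planted feature.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_drugs = 30, n_foods = 100, seed = 42,
                             class_proportions = c(0.20, 0.33, 0.47),
                             label_noise = 0.02,
                             planted_features = c("VSAEstate9+VSAEstate9",
                                                  "drug.EstateVSA8"),
                             planted_weights = NULL) {
  .assert(label_noise >= 0 && label_noise <= 0.5,
          "label_noise must be in [0, 0.5]")
  planted_features <- resolve_pair_feature(planted_features)
  planted_weights <- planted_weights %||% rep(1, length(planted_features))
  .assert(length(planted_weights) == length(planted_features),
          "one weight per planted feature required")
  structure(list(n_drugs = n_drugs, n_foods = n_foods, seed = seed,
                 class_proportions = class_proportions,
                 label_noise = label_noise,
                 planted_features = planted_features,
                 planted_weights = planted_weights),
            class = "synthetic_config")
}

#' Recompute planted labels from a generation rule
#'
#' @param table a `pair_feature_table`.
#' @param rule the `rule` record returned by
#'   [generate_planted_dataset()].
#' @return Integer labels implied by the rule (before noise).
#' @export
planted_labels <- function(table, rule) {
  Z <- as.matrix(table[, rule$planted_features, drop = FALSE])
  Z <- sweep(sweep(Z, 2, rule$center, "-"), 2, rule$scale, "/")
  score <- as.vector(Z %*% rule$weights)
  as.integer(cut(score, c(-Inf, rule$cutpoints, Inf), labels = FALSE)) - 1L
}

#' Generate the planted-signal benchmark dataset
#'
#' Builds drug and food libraries with the fragment grammar, computes real
#' MOE-type descriptors, featurizes the full Cartesian product of pairs,
#' and assigns each pair a class by thresholding a linear score over the
#' planted pair features at its empirical tertiles (low third = negative 0,
#' middle = positive 1, high = non-significant 2). A `label_noise` fraction
#' of labels is then flipped uniformly to another class. Because the
#' descriptors are computed from real structures, the planted dataset
#' carries realistic feature correlation for recovery experiments.
#'
#' @param config a [synthetic_config()].
#' @return `list(features = pair_feature_table (with noisy labels),
#'   truth = integer pre-noise labels, rule = generation record
#'   (planted features, weights, centers, scales, cutpoints),
#'   drugs = , foods = compound sets)`.
#' @export
generate_planted_dataset <- function(config = synthetic_config()) {
  .assert(inherits(config, "synthetic_config"), "config must be a synthetic_config")
  drugs <- generate_compound_library(config$n_drugs, config$seed, "drug")
  foods <- generate_compound_library(config$n_foods, config$seed, "food")
  ddesc <- compute_moe_descriptors(drugs)
  fdesc <- compute_moe_descriptors(foods)
  pairs <- tibble::tibble(
    drug_id = rep(drugs$id, each = nrow(foods)),
    food_id = rep(foods$id, times = nrow(drugs))
  )
  features <- featurize_pairs(pairs, ddesc, fdesc)
  Zraw <- as.matrix(features[, config$planted_features, drop = FALSE])
  center <- colMeans(Zraw)
  scale_ <- apply(Zraw, 2, stats::sd)
  if (any(scale_ == 0)) {
    .stopf("degenerate planted score: feature %s is constant; choose different planted features",
           config$planted_features[which(scale_ == 0)[1]])
  }
  score <- as.vector(sweep(sweep(Zraw, 2, center, "-"), 2, scale_, "/") %*%
                       config$planted_weights)
  if (stats::sd(score) == 0) {
    .stopf("degenerate planted score (constant); choose different planted features")
  }
  cutpoints <- unname(stats::quantile(score, c(1 / 3, 2 / 3)))
  truth <- as.integer(cut(score, c(-Inf, cutpoints, Inf), labels = FALSE)) - 1L
  labels <- truth
  n_flip <- round(config$label_noise * length(truth))
  if (n_flip > 0) {
    .with_seed(derive_seed(config$seed, "label-noise"), {
      flip <- sample(length(truth), n_flip)
      labels[flip] <- vapply(labels[flip],
                             function(l) sample(setdiff(0:2, l), 1),
                             integer(1))
    })
  }
  features$label <- labels
  rule <- list(planted_features = config$planted_features,
               weights = config$planted_weights,
               center = center, scale = scale_, cutpoints = cutpoints,
               mapping = c(low = 0L, mid = 1L, high = 2L))
  list(features = features, truth = truth, rule = rule,
       drugs = drugs, foods = foods)
}
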