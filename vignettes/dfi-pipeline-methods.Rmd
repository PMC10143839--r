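---
title: "Predicting drug-food interactions from chemical structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-food interactions from chemical structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A drug-food interaction (DFI) is the effect a food constituent has on a
drug's pharmacokinetics, pharmacodynamics, or on patient safety: grapefruit
furanocoumarins inhibiting intestinal CYP3A4, vitamin K antagonizing
warfarin, ethanol potentiating CNS depressants. Curated annotation
databases describe these effects in free text for a modest number of drugs,
while the space of drug x food-constituent pairs is astronomically larger.
dfikit implements a structure-based shortcut: learn a multiclass model that
maps the chemical structures of a (drug, food constituent) pair — given
only as SMILES strings — to one of three interaction classes:

* **negative (0)** — the food impairs the drug or harms the patient;
* **positive (1)** — the food helps absorption or tolerability;
* **non-significant (2)** — no clinically meaningful interaction.

The model's output is rendered as one of three fixed recommendation
sentences ("X should not / could / may be taken with food containing Y").

## Pipeline overview

1. **Ingestion** (`read_compound_table`, `drop_invalid_and_duplicates`):
   compound tables are canonicalized with RDKit; rows with missing or
   unparseable SMILES are counted, not raised, and duplicates (by canonical
   SMILES, first occurrence wins) are removed.
2. **Structural deduplication** (`greedy_dissimilarity_filter`): Morgan
   fingerprints (radius 2, 2048 bits) and a greedy target/query sweep in
   input order; each surviving compound removes every later compound with
   Tanimoto similarity >= 0.75. Applied to the food library, whose source
   databases are full of near-duplicate natural products.
3. **Labeling** (`label_drugs`, `build_pairs`): free-text annotations are
   matched against a trigger lexicon (below); drug-level labels broadcast
   over all foods to form labeled pairs.
4. **Featurization** (`compute_moe_descriptors`, `featurize_pairs`): 60
   MOE-type descriptors per molecule expand into 3780 features per pair;
   pairs with identical feature means are dropped (`dedup_by_mean`).
5. **Selection** (`run_cascade`): variance threshold 0.8, standardization,
   Pearson pruning at \|r\| > 0.75, LASSO at penalty 0.001, ridge-based
   RFECV.
6. **Modeling** (`split_dataset`, `randomized_search`, `train_final`,
   `evaluate_model`): 0.50/0.375/0.125 train/validation/test split,
   randomized hyperparameter search (5 candidates, 5-fold CV on the
   validation split), per-class one-vs-rest accuracy/recall/precision/F1.
7. **Interpretation** (`attribute_predictions`, `summarize_attribution`):
   exact additive TreeSHAP-style attributions for the boosted-tree model.

## The annotation lexicon

The labeler is deliberately shallow: normalized-substring triggers plus
small keyword regexes, no NLP. Evaluation order for a single sentence:

1. explicit negative triggers ("avoid", "take separately from meals",
   "take on an empty stomach", "take before a meal", harm phrases);
2. pharmacokinetic *decrease* (reduced absorption/bioavailability/peak
   concentration, increased time to peak) **and** an adverse-effect
   mention -> negative;
3. explicit positive triggers ("take with food", "take after meals",
   benefit phrases such as "reduce nausea");
4. pharmacokinetic *increase* with **no** adverse-effect mention ->
   positive;
5. non-significant triggers ("take with or without food", "take
   consistently with regard to food");
6. anything else -> non-significant;
7. a sentence matching only "take at the same time every day" is ignored.

Negated adverse mentions ("no adverse effect or toxicity has been
observed") are scrubbed before step 2/4, since that phrasing is part of the
*positive* definition. When one drug carries conflicting annotations the
drug-level label takes the safety-first precedence negative > positive >
non-significant; a drug whose annotations are all ignored contributes no
pairs. A packaged golden table (`inst/extdata/annotation_golden.csv`,
27 hand-labeled cases including the conflict and ignore-override rules)
pins this behavior in the tests.

Broadcasting the drug-level label to *all* foods is a modeling
simplification: an "avoid alcohol" annotation labels every (drug, food)
pair negative, not just ethanol-containing foods. It is what makes
pair-level supervision possible at scale, and it is the pipeline's largest
source of label noise on real data.

## The descriptor registry and pair expansion

Each molecule gets 60 two-dimensional descriptors in seven families:
`slogPVSA0..11`, `MRVSA0..9`, `PEOEVSA0..13`, `EstateVSA0..10`,
`VSAEstate0..10`, `LabuteASA`, `MTPSA`. The VSA families partition the
molecule's approximate van der Waals surface area into bins of an atomic
property (Crippen logP, Crippen molar refractivity, Gasteiger partial
charge, electrotopological state); `LabuteASA` is the total surface and
`MTPSA` the Ertl topological polar surface area. The atomic contributions
come from RDKit via a batched subprocess bridge; the package only assembles
the registry. One registry subtlety: modern RDKit bins `VSA_EState` over 10
surface-area bins, but the 11-slot convention (indices 0..10, with
`VSAEstate10` a real, selectable feature) comes from binning over the
E-state bin edges; the bridge passes those edges explicitly to reproduce
the 11-slot family.

All seven families are conformation-independent; no 3D embedding is
computed anywhere.

A pair of descriptor vectors (drug `d`, food `f`) expands to 3780 features:
120 singles (`drug.X`, `food.X`), 60 same-name sums (`X+X` = `d[X] + f[X]`)
and 3600 ordered products (`X*Y` = `d[X] * f[Y]`). This is the unique
natural scheme that reaches 3780 from 60 per-molecule descriptors while
producing exactly the three name shapes (bare names, `X+X`, `X*Y`) that
appear in published selected-feature lists for this problem; we flag it as
an inference, and `resolve_pair_feature()` maps a bare display name to its
`drug.`-prefixed registry entry.

The Lorentz-Lorenz relation MR = ((n^2-1)/(n^2+2)) (MW/d) is exposed as
`molar_refractivity()` for bulk data; the `MRVSA*` bins themselves use
Crippen atomic contributions, because refractive index and density are not
derivable from a SMILES.

## The selection cascade

* **Variance threshold** (0.8) runs on raw, unstandardized values —
  deliberately so; it removes descriptor bins that are near-constant across
  pairs.
* **Standardization** is fit on training rows only and reused for every
  later transformation (validation, test, prediction); constant features
  map to zero.
* **Pearson pruning** (\|r\| > 0.75) sweeps correlated pairs in decreasing
  \|r\| and drops the member with lower outcome relevance, measured as the
  maximum over classes of \|r\| between the feature and the one-vs-rest
  class indicator. Ties keep the earlier registry column. Undefined
  correlations (constant features) count as zero with a warning.
* **LASSO** is an L1-penalized multinomial logistic regression at a fixed
  penalty of 0.001 (a feature survives if any class coefficient is
  nonzero). The multinomial encoding is a design choice: a plain lasso on
  an integer-coded 3-class label would impose a spurious ordering. With
  well-separated classes the unpenalized multinomial loss has no finite
  minimum, so the solver runs a geometric warm-start path down to the
  target penalty with a capped iteration count (convergence cap reached ->
  glmnet warning, capped coefficients used, deterministically).
* **RFECV** eliminates one feature per round, ranked by the aggregate
  coefficient magnitude of a ridge classifier (multi-response gaussian
  ridge on the one-hot label matrix, argmax prediction, penalty chosen by
  internal cross-validation over a fixed grid), and keeps the feature count
  with the best stratified 5-fold CV accuracy, ties resolved toward fewer
  features.

Survivor sets are nested across stages by construction, and everything is
computed from the training rows alone.

Two parameters deserve a note: the LASSO penalty is quoted in this problem
domain both as 0.001 and as 0.01; we default to 0.001 and expose it in
`cascade_config()`. And a correlation-pruning stage can be read either as
purely pairwise or as an additional relevance filter; we implement pairwise
pruning with relevance deciding each pair's loser.

## Modeling choices

Model families: gradient-boosted trees (xgboost), random forest and
extremely randomized trees (ranger), and a single-hidden-layer perceptron
(nnet). A light-gradient-boosting family is not shipped; the
gradient-boosted tree model is the reference model throughout, and the
family set covers the bagging/boosting/neural contrast that matters for the
comparison. All fits are single-threaded with explicit seeds, so refits are
bit-reproducible.

The randomized search reads "five iterations" as five sampled parameter
settings, drawn uniformly without replacement from the grid (Cartesian
product of the candidate lists; defaults: n_estimators {50,100,150,200},
max_depth {3,4,5,6,8,10,12,15}, gamma {0..0.4}, colsample_bytree
{0.3,0.4,0.5,0.7}, min_child_weight {1,3,5,7}, learning_rate {0.05..0.3}),
and — mirroring the unusual protocol this design follows — evaluates them
by 5-fold CV *on the validation split*, not the training split.

Per-class metrics are one-vs-rest: Accuracy (TP+TN)/n, Recall TP/(TP+FN),
Precision TP/(TP+FP), F1 = 2PR/(P+R). A zero denominator reports 0 with a
warning rather than NaN.

## The synthetic study

Real inputs (licensed annotation and food-composition databases) cannot be
shipped, so the package generates its own study:

* **Molecules** come from a fragment grammar (alkyl starts, branch
  substituents O/N/S/halogen/acid/amide/nitrile/nitro/CF3, aromatic and
  aliphatic rings, polar terminals) whose concatenations are valid SMILES
  by construction; distinctness is enforced on canonical SMILES. This spans
  enough chemistry that all seven descriptor families vary.
* **Annotations** are sampled from the trigger lexicon with a known class
  per drug (default mix 0.20/0.33/0.47 negative/positive/non-significant,
  the imbalance typical of curated DFI corpora), so the labeler can be
  tested closed-loop at 100% recovery.
* **The planted pair dataset** (default: 30 drugs x 100 foods = 3000
  pairs, seed 42) computes *real* descriptors for the generated molecules,
  featurizes all pairs, and assigns the true class by cutting a linear
  score over two planted features at its empirical tertiles (low third ->
  negative, middle -> positive, top -> non-significant), then flips 2% of
  labels uniformly. Tertiles give a controlled 3-class structure without
  hand-tuned cutpoints; 2% is a realistic annotation-error rate.

The default planted features are `VSAEstate9+VSAEstate9` (a cross-molecule
electrotopological surface sum) and `drug.EstateVSA8`. They were chosen for
*identifiability*: the pair-feature space is intrinsically collinear (every
feature has a neighbor with \|r\| around 0.7), and a planted feature whose
label signal is exceeded by a >0.75-correlated proxy cannot be recovered by
relevance-based pruning — no selection method could distinguish them. Across
generator seeds, each default planted feature carries more label relevance
than everything in its own pruning neighborhood, which is precisely the
regime in which recovery is a meaningful test. Three-or-more planted
features under equal weights dilute each feature's marginal relevance below
its proxies and make recovery ill-posed; the two-feature default keeps the
study honest.

What the synthetic study does *not* emulate: real annotation language
beyond the lexicon, the per-food specificity that broadcasting ignores,
drug-like structural complexity (macrocycles, stereo-rich natural
products), and dataset-scale class imbalance. A model passing the planted
study demonstrates that the pipeline's machinery — featurization,
leakage-free selection, tuning, evaluation, attribution — works as
specified, not that the shipped defaults generalize to any particular real
database.

## Numerical conventions

* Two all-zero fingerprints have Tanimoto similarity 1 (identical
  emptiness), with a warning, so featureless molecules collapse to one
  representative.
* Pair means for `dedup_by_mean` are rounded to 12 significant digits
  before equality comparison; the summation order is fixed by the column
  registry, and the rounding absorbs cross-platform last-bit drift.
* Variance thresholding keeps a feature whose variance equals the
  threshold exactly (the rule drops "lower than").
* `max.col` ties in argmax predictions resolve to the first (lowest)
  class; correlation-prune relevance ties keep the earlier column.
* All derived seeds are produced by hashing a stream label with the master
  seed (`derive_seed`), keeping every stage's randomness independent and
  below 2^31.
* Salts and stereochemistry are left untouched during canonicalization;
  origin-class metadata (organic/inorganic/unknown) is carried but never
  used in computation.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the reference study at 30 x
100 pairs with the full 3780-feature cascade, a 200-fingerprint filter
oracle comparison, 100 random prediction vectors for metric equivalence,
and 10 smaller numeric planted datasets for cascade nestedness. These sizes
exercise every code path at full feature dimensionality while keeping a
complete run in the minutes range on a single core.

## Known limitations

* The labeler is a lexicon, not a language model; paraphrases outside the
  trigger vocabulary fall back to non-significant by design.
* Drug-level broadcast labels every food identically for a given drug;
  per-food restriction requires a targeted food map not shipped here.
* Severity is out of scope: a negative prediction says nothing about how
  harmful the interaction is.
* Descriptor values depend on the toolkit's atomic parameterizations;
  canonical SMILES and descriptor values from other toolkits (or other
  RDKit major versions) may differ, which is why the toolkit is recorded in
  provenance and pinned by the bridge.
* SDF input is not implemented; compound tables are CSV/TSV.
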