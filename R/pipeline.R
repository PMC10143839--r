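#' Pipeline configuration
#'
#' Collects the thresholds and seeds of every stage: Tanimoto 0.75 for the
#' structural-redundancy filter, variance 0.8 / Pearson 0.75 / LASSO 0.001
#' for the selection cascade, the 0.50/0.375/0.125 split, the randomized
#' search grid, and the model family.
#'
#' @param synthetic a [synthetic_config()] describing the input data.
#' @param tanimoto_threshold structural-similarity rejection threshold.
#' @param cascade a [cascade_config()].
#' @param split a [split_spec()].
#' @param family model family (default `"xgboost"`).
#' @param grid hyperparameter grid for [randomized_search()].
#' @param n_candidates randomized-search candidates.
#' @param seed master seed (stages derive their own streams from it).
#' @return A `pipeline_config` list (validated).
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            tanimoto_threshold = 0.75,
                            cascade = cascade_config(),
                            split = split_spec(),
                            family = "xgboost",
                            grid = default_hyper_grid(),
                            n_candidates = 5,
                            seed = 42) {
  .assert(tanimoto_threshold > 0 && tanimoto_threshold <= 1,
          "tanimoto_threshold must be in (0, 1]")
  .assert(family %in% dfi_model_families(),
          "family must be one of: %s", paste(dfi_model_families(), collapse = ", "))
  structure(list(synthetic = synthetic,
                 tanimoto_threshold = tanimoto_threshold,
                 cascade = cascade, split = split, family = family,
                 grid = grid, n_candidates = n_candidates, seed = seed),
            class = "pipeline_config")
}

#' Run the end-to-end pipeline on synthetic data
#'
#' One-command demo of the whole method: generate compound libraries and a
#' planted-signal pair dataset, split it, run the four-stage selection
#' cascade on the training rows, tune the classifier by randomized search
#' on the validation rows, train the final model, evaluate it on the test
#' rows, attribute its predictions, and render recommendation sentences
#' for a sample of test pairs. If `out_dir` is given, stage artifacts and
#' a manifest (seeds, stage checksums) are written there.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for artifacts.
#' @return List with `dataset`, `splits`, `cascade`, `search`, `model`,
#'   `evaluation`, `attribution`, `recommendations`, and `manifest`.
#' @export
run_dfi_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  seed <- config$seed

  dataset <- generate_planted_dataset(config$synthetic)
  dd <- dedup_by_mean(dataset$features)
  splits <- split_dataset(dd$table, config$split)

  tr <- pair_feature_matrix(splits$train)
  cascade <- run_cascade(tr$X, tr$y, config$cascade)
  sel <- cascade$survivors

  prep <- function(tbl) {
    m <- pair_feature_matrix(tbl)
    list(X = apply_standardizer(
      cascade$standardizer,
      m$X[, cascade$reports$variance$survivors, drop = FALSE]
    )[, sel, drop = FALSE], y = m$y, ids = m$ids)
  }
  trn <- prep(splits$train); val <- prep(splits$validation); tst <- prep(splits$test)

  search <- randomized_search(config$family, config$grid, val$X, val$y,
                              n_candidates = config$n_candidates,
                              seed = derive_seed(seed, "search"))
  model <- train_final(config$family, search$best_params, trn$X, trn$y,
                       seed = derive_seed(seed, "train"))
  evaluation <- evaluate_model(model, tst$X, tst$y)

  attribution <- NULL
  if (config$family == "xgboost") {
    attr_m <- attribute_predictions(model, tst$X)
    attribution <- summarize_attribution(attr_m, tst$X)
  }

  take <- utils::head(seq_len(nrow(tst$X)), 10)
  name_of <- function(ids, set) set$name[match(ids, set$id)]
  recommendations <- recommend_batch(
    model, tst$X[take, , drop = FALSE],
    name_of(tst$ids$drug_id[take], dataset$drugs),
    name_of(tst$ids$food_id[take], dataset$foods))

  manifest <- list(
    seed = seed,
    n_pairs = nrow(dataset$features),
    n_after_dedup = nrow(dd$table),
    split_sizes = vapply(splits, nrow, integer(1)),
    cascade_path = vapply(cascade$reports, `[[`, integer(1), "n_out"),
    family = config$family,
    best_params = search$best_params,
    test_accuracy = evaluation$overall_accuracy
  )

  result <- list(dataset = dataset, splits = splits, cascade = cascade,
                 search = search, model = model, evaluation = evaluation,
                 attribution = attribution,
                 recommendations = recommendations, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_compound_table(dataset$drugs, file.path(out_dir, "drugs.csv"))
    write_compound_table(dataset$foods, file.path(out_dir, "foods.csv"))
    utils::write.csv(recommendations,
                     file.path(out_dir, "recommendations.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(manifest = manifest,
           survivors = cascade$survivors,
           per_class = evaluation$per_class,
           checksums = as.list(tools::md5sum(list.files(out_dir,
                                                        full.names = TRUE)))),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
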