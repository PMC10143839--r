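#' Dataset split specification
#'
#' Fractions default to the train / validation (hyperparameter tuning) /
#' test layout 0.50 / 0.375 / 0.125.
#'
#' @param train,validation,test positive fractions summing to 1.
#' @param seed split seed.
#' @param stratify stratify the split by label (default `FALSE`, plain
#'   random split).
#' @return A `split_spec` list.
#' @export
split_spec <- function(train = 0.50, validation = 0.375, test = 0.125,
                       seed = 42, stratify = FALSE) {
  f <- c(train = train, validation = validation, test = test)
  .assert(all(f > 0), "all fractions must be positive")
  .assert(abs(sum(f) - 1) <= 1e-9, "fractions must sum to 1")
  structure(list(fractions = f, seed = seed, stratify = stratify),
            class = "split_spec")
}

#' Split a dataset into train / validation / test
#'
#' Disjoint, exhaustive, reproducible for a fixed seed. Sizes are
#' `round(n * fraction)` for train and validation with the remainder going
#' to test; a split that would be empty is a contract error.
#'
#' @param table data frame (typically a `pair_feature_table`).
#' @param spec a [split_spec()].
#' @return `list(train = , validation = , test = )` of row subsets.
#' @export
split_dataset <- function(table, spec = split_spec()) {
  n <- nrow(table)
  .assert(n > 0, "cannot split an empty table")
  assign_split <- function(idx) {
    m <- length(idx)
    n_tr <- round(m * spec$fractions[["train"]])
    n_va <- round(m * spec$fractions[["validation"]])
    out <- rep("test", m)
    out[seq_len(n_tr)] <- "train"
    if (n_va > 0) out[n_tr + seq_len(min(n_va, m - n_tr))] <- "validation"
    setNames(out, idx)
  }
  lab <- .with_seed(spec$seed, {
    if (isTRUE(spec$stratify) && "label" %in% names(table)) {
      res <- character(n)
      for (cl in unique(table$label)) {
        idx <- sample(which(table$label == cl))
        res[idx] <- assign_split(idx)
      }
      res
    } else {
      res <- character(n)
      idx <- sample.int(n)
      res[idx] <- assign_split(idx)
      res
    }
  })
  out <- list(train = table[lab == "train", , drop = FALSE],
              validation = table[lab == "validation", , drop = FALSE],
              test = table[lab == "test", , drop = FALSE])
  .assert(all(vapply(out, nrow, integer(1)) > 0),
          "fractions leave an empty split for n = %d", n)
  for (i in seq_along(out)) class(out[[i]]) <- class(table)
  out
}

#' Supported classifier families
#'
#' Gradient-boosted trees (xgboost), random forest and extremely randomized
#' trees (ranger), and a single-hidden-layer multilayer perceptron (nnet).
#'
#' @return Character vector of family names.
#' @export
dfi_model_families <- function() {
  c("xgboost", "random_forest", "extra_trees", "mlp")
}

#' Default hyperparameter grid
#'
#' Candidate lists for randomized search over the gradient-boosting
#' parameters: `n_estimators`, `max_depth`, `gamma`, `colsample_bytree`,
#' `min_child_weight`, `learning_rate`. Tree-bagging families consume the
#' subset that applies to them (`n_estimators`, `max_depth`); the
#' perceptron consumes `n_estimators` as hidden-layer size candidates.
#'
#' @return Named list of candidate vectors.
#' @export
default_hyper_grid <- function() {
  list(
    n_estimators = c(50, 100, 150, 200),
    max_depth = c(3, 4, 5, 6, 8, 10, 12, 15),
    gamma = c(0.0, 0.1, 0.2, 0.3, 0.4),
    colsample_bytree = c(0.3, 0.4, 0.5, 0.7),
    min_child_weight = c(1, 3, 5, 7),
    learning_rate = c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3)
  )
}

.default_params <- function(family) {
  switch(family,
    xgboost = list(n_estimators = 100, max_depth = 6, gamma = 0,
                   colsample_bytree = 1, min_child_weight = 1,
                   learning_rate = 0.1),
    random_forest = list(n_estimators = 200, max_depth = 0),
    extra_trees = list(n_estimators = 200, max_depth = 0),
    mlp = list(size = 8, decay = 1e-3, maxit = 300)
  )
}

.fit_family <- function(family, X, y, params, seed) {
  classes <- sort(unique(y))
  p <- utils::modifyList(.default_params(family), params)
  if (family == "xgboost") {
    dtrain <- xgboost::xgb.DMatrix(X, label = match(y, classes) - 1L)
    booster <- xgboost::xgb.train(
      params = list(objective = "multi:softprob",
                    num_class = length(classes),
                    max_depth = as.integer(p$max_depth),
                    gamma = p$gamma,
                    colsample_bytree = p$colsample_bytree,
                    min_child_weight = p$min_child_weight,
                    eta = p$learning_rate,
                    nthread = 1, seed = seed),
      data = dtrain, nrounds = as.integer(p$n_estimators), verbose = 0)
    list(fit = booster, classes = classes)
  } else if (family %in% c("random_forest", "extra_trees")) {
    fit <- ranger::ranger(
      x = as.data.frame(X), y = factor(y, levels = classes),
      num.trees = as.integer(p$n_estimators),
      max.depth = as.integer(p$max_depth),
      splitrule = if (family == "extra_trees") "extratrees" else "gini",
      probability = TRUE, seed = seed, num.threads = 1)
    list(fit = fit, classes = classes)
  } else if (family == "mlp") {
    Yh <- nnet::class.ind(factor(y, levels = classes))
    fit <- .with_seed(seed, nnet::nnet(
      X, Yh, size = as.integer(p$size), decay = p$decay,
      maxit = as.integer(p$maxit), softmax = TRUE, trace = FALSE,
      MaxNWts = 100000))
    list(fit = fit, classes = classes)
  } else {
    .stopf("unknown model family: %s", family)
  }
}

.predict_prob <- function(model, X) {
  fam <- model$family
  classes <- model$classes
  if (fam == "xgboost") {
    pr <- predict(model$fit, xgboost::xgb.DMatrix(X))
    matrix(pr, ncol = length(classes), byrow = is.null(dim(pr)))
  } else if (fam %in% c("random_forest", "extra_trees")) {
    unname(predict(model$fit, as.data.frame(X),
                   num.threads = 1)$predictions)
  } else {
    pr <- predict(model$fit, X)
    matrix(pr, ncol = length(classes))
  }
}

#' Train a final classifier
#'
#' @param family one of [dfi_model_families()].
#' @param params named list of hyperparameters (unspecified entries fall
#'   back to family defaults; see [default_hyper_grid()]).
#' @param X numeric feature matrix with column names (the feature
#'   registry of the model).
#' @param y integer class labels.
#' @param seed training seed; fits are single-threaded and reproducible.
#' @return A `dfi_model`.
#' @export
train_final <- function(family, params, X, y, seed = 42) {
  family <- match.arg(family, dfi_model_families())
  .assert(is.matrix(X) && !is.null(colnames(X)), "X must be a named matrix")
  .assert(all(is.finite(X)), "non-finite feature values in X")
  .assert(nrow(X) == length(y), "X rows must match y")
  fitted <- .fit_family(family, X, y, params, seed)
  structure(list(family = family, params = params, fit = fitted$fit,
                 classes = fitted$classes, feature_names = colnames(X),
                 seed = seed),
            class = "dfi_model")
}

#' @method print dfi_model
#' @export
print.dfi_model <- function(x, ...) {
  cat(sprintf("<dfi_model> %s on %d features; classes: %s\n",
              x$family, length(x$feature_names),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict classes or probabilities from a trained model
#'
#' Refuses feature matrices whose columns do not match the model's feature
#' registry in name and order.
#'
#' @param object a `dfi_model`.
#' @param newdata numeric matrix with the model's feature columns.
#' @param type `"class"` (integer labels) or `"prob"` (class probability
#'   matrix).
#' @param ... unused.
#' @export
predict.dfi_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  .assert(is.matrix(newdata), "newdata must be a matrix")
  .assert(identical(colnames(newdata), object$feature_names),
          "feature registry mismatch between model and newdata")
  pr <- .predict_prob(object, newdata)
  if (type == "prob") {
    colnames(pr) <- as.character(object$classes)
    return(pr)
  }
  object$classes[max.col(pr, ties.method = "first")]
}

#' K-fold cross-validated accuracy of one classifier family
#'
#' Stratified k-fold (plain leave-one-out when `k = n`); every training
#' fold must contain at least two classes.
#'
#' @param family model family.
#' @param X,y features and labels.
#' @param k folds (default 5).
#' @param seed fold and fit seed.
#' @param params hyperparameters passed to the family.
#' @return `list(mean, sd, fold_accuracy)`.
#' @export
cross_validate <- function(family, X, y, k = 5, seed = 42, params = list()) {
  n <- length(y)
  .assert(k >= 2 && k <= n, "k must be in [2, n]")
  fold <- if (k == n) seq_len(n) else .make_folds(y, k, derive_seed(seed, "cv-folds"))
  accs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    .assert(length(unique(y[tr])) >= 2,
            "a training fold has fewer than two classes; reduce k")
    m <- train_final(family, params, X[tr, , drop = FALSE], y[tr], seed = seed)
    mean(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  list(mean = mean(accs), sd = stats::sd(accs), fold_accuracy = accs)
}

#' Randomized hyperparameter search
#'
#' Samples `n_candidates` distinct parameter combinations uniformly from
#' the grid's Cartesian product and scores each by k-fold cross-validation
#' on the supplied (validation) rows; the best score wins, ties going to
#' the earlier-sampled candidate.
#'
#' @param family model family.
#' @param grid named list of candidate vectors (see
#'   [default_hyper_grid()]).
#' @param X_val,y_val validation features and labels.
#' @param n_candidates sampled combinations (default 5; capped at the grid
#'   size with a warning).
#' @param folds CV folds per candidate.
#' @param seed sampling and CV seed.
#' @return `list(best_params, best_score, results)` where `results` is a
#'   tibble of the evaluated candidates.
#' @export
randomized_search <- function(family, grid = default_hyper_grid(),
                              X_val, y_val, n_candidates = 5, folds = 5,
                              seed = 42) {
  .assert(length(grid) > 0 && all(lengths(grid) > 0), "grid must be non-empty")
  sizes <- lengths(grid)
  total <- prod(sizes)
  if (n_candidates > total) {
    .warnf("n_candidates (%d) exceeds grid size (%d); capped", n_candidates,
           total)
    n_candidates <- total
  }
  picks <- .with_seed(derive_seed(seed, "search-sample"),
                      sample(total, n_candidates))
  decode <- function(ix) {
    ix <- ix - 1
    out <- list()
    for (j in seq_along(grid)) {
      out[[names(grid)[j]]] <- grid[[j]][ix %% sizes[j] + 1]
      ix <- ix %/% sizes[j]
    }
    out
  }
  candidates <- lapply(picks, decode)
  scores <- vapply(seq_along(candidates), function(i) {
    cross_validate(family, X_val, y_val, k = folds,
                   seed = derive_seed(seed, paste0("search-cv", i)),
                   params = candidates[[i]])$mean
  }, numeric(1))
  best <- which.max(scores)   # first maximum = earliest sampled
  results <- tibble::as_tibble(do.call(rbind, lapply(candidates, as.data.frame)))
  results$score <- scores
  list(best_params = candidates[[best]], best_score = scores[best],
       results = results)
}

#' Evaluate predictions with per-class one-vs-rest metrics
#'
#' Builds the true-by-predicted confusion matrix and, for each class, the
#' one-vs-rest TP/TN/FP/FN with Accuracy `(TP+TN)/n`, Recall `TP/(TP+FN)`,
#' Precision `TP/(TP+FP)`, and F1 `2PR/(P+R)`. A zero denominator yields 0
#' with a warning.
#'
#' @param truth,predicted integer label vectors of equal length.
#' @param classes class universe (default `0:2`).
#' @return An `evaluation_report`: list with `confusion` (matrix),
#'   `per_class` (tibble), and `overall_accuracy`.
#' @export
evaluate_predictions <- function(truth, predicted, classes = 0:2) {
  .assert(length(truth) == length(predicted),
          "truth and predictions differ in length")
  n <- length(truth)
  .assert(n > 0, "empty evaluation set")
  ft <- factor(truth, levels = classes)
  fp <- factor(predicted, levels = classes)
  cm <- table(truth = ft, predicted = fp)
  per <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fpv <- sum(cm[, i]) - tp
    tn <- n - tp - fn - fpv
    div <- function(num, den, what) {
      if (den == 0) {
        .warnf("zero denominator for %s of class %s; reporting 0", what,
               classes[i])
        return(0)
      }
      num / den
    }
    recall <- div(tp, tp + fn, "recall")
    precision <- div(tp, tp + fpv, "precision")
    f1 <- div(2 * precision * recall, precision + recall, "F1")
    tibble::tibble(class = classes[i], TP = tp, TN = tn, FP = fpv, FN = fn,
                   accuracy = (tp + tn) / n, recall = recall,
                   precision = precision, f1 = f1)
  })
  structure(list(confusion = unclass(cm),
                 per_class = do.call(rbind, per),
                 overall_accuracy = mean(truth == predicted)),
            class = "evaluation_report")
}

#' @method print evaluation_report
#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> overall accuracy %.4f\n",
              x$overall_accuracy))
  print(x$per_class)
  invisible(x)
}

#' Evaluate a trained model on labeled data
#'
#' @param model a `dfi_model`.
#' @param X feature matrix matching the model registry.
#' @param y true labels.
#' @return An [evaluate_predictions()] report over the model's classes.
#' @export
evaluate_model <- function(model, X, y) {
  evaluate_predictions(y, predict(model, X), classes = model$classes)
}
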