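#' Selection stage report
#'
#' Audit record of one feature-selection stage: the stage name, feature
#' counts in and out, parameters, and the ordered survivor list (a subset of
#' the stage's input features, input order preserved).
#'
#' @param stage one of `"variance"`, `"pearson"`, `"lasso"`, `"rfecv"`.
#' @param n_in number of features entering the stage.
#' @param survivors character vector of retained feature names.
#' @param params parameter record.
#' @return Object of class `selection_report`.
#' @export
selection_report <- function(stage, n_in, survivors, params = list()) {
  .assert(length(survivors) <= n_in, "survivors exceed stage input")
  structure(list(stage = stage, n_in = as.integer(n_in),
                 n_out = length(survivors),
                 params = params, survivors = survivors),
            class = "selection_report")
}

#' @method print selection_report
#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %s: %d -> %d features\n",
              x$stage, x$n_in, x$n_out))
  invisible(x)
}

#' Variance-threshold feature selection
#'
#' Drops features whose sample variance, computed on the raw
#' (unstandardized) training values, is strictly lower than the threshold.
#' A feature with variance exactly equal to the threshold is kept.
#'
#' @param X numeric matrix (rows = training samples) with column names.
#' @param threshold variance cutoff (default 0.8).
#' @return A [selection_report] with stage `"variance"`.
#' @export
variance_threshold_select <- function(X, threshold = 0.8) {
  .assert(is.matrix(X) && nrow(X) >= 2, "X must be a matrix with >= 2 rows")
  v <- apply(X, 2, stats::var)
  selection_report("variance", ncol(X), colnames(X)[v >= threshold],
                   list(threshold = threshold))
}

#' Fit a standardization model on training rows
#'
#' Learns per-feature mean and standard deviation from the training rows
#' only; [apply_standardizer()] then maps any row set to z-scores
#' `(x - mean) / sd`. Constant features (sd 0) transform to 0.
#'
#' @param X_train numeric training matrix with column names.
#' @return Object of class `standardizer` (fields `mean`, `sd`).
#' @export
fit_standardizer <- function(X_train) {
  .assert(is.matrix(X_train), "X_train must be a matrix")
  structure(list(mean = colMeans(X_train),
                 sd = apply(X_train, 2, stats::sd)),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param model a fitted `standardizer`.
#' @param X matrix to transform (same columns as the training matrix).
#' @return Standardized matrix of the same shape as `X`.
#' @export
apply_standardizer <- function(model, X) {
  .assert(inherits(model, "standardizer"), "model must be a standardizer")
  .assert(identical(colnames(X), names(model$mean)),
          "columns do not match the standardizer's training columns")
  s <- ifelse(model$sd == 0, 1, model$sd)
  Z <- sweep(sweep(X, 2, model$mean, "-"), 2, s, "/")
  Z[, model$sd == 0] <- 0
  Z
}

# |Pearson r| of each feature with the one-vs-rest indicator of each class,
# maximized over classes; the stage's "contribution to the outcome".
.class_relevance <- function(X, y) {
  classes <- sort(unique(y))
  R <- vapply(classes,
              function(cl) suppressWarnings(abs(cor(X, as.numeric(y == cl)))),
              numeric(ncol(X)))
  rel <- apply(matrix(R, ncol = length(classes)), 1, max)
  rel[!is.finite(rel)] <- 0
  rel
}

#' Pearson correlation pruning
#'
#' For every feature pair whose absolute Pearson correlation exceeds the
#' threshold, rejects the member that contributes less to the outcome.
#' Pairs are swept in decreasing `|r|` (ties broken by column order); a pair
#' is skipped if either member was already dropped. Relevance to the outcome
#' is the maximum over classes of `|r|` between the feature and the
#' one-vs-rest class indicator; relevance ties drop the later column.
#' Constant features (undefined correlations) are treated as `r = 0` with a
#' warning.
#'
#' @param X standardized numeric training matrix with column names.
#' @param y integer class labels aligned with rows of `X`.
#' @param r_threshold correlation cutoff (default 0.75; pruning applies to
#'   `|r|` strictly greater).
#' @return A [selection_report] with stage `"pearson"`.
#' @export
correlation_prune <- function(X, y, r_threshold = 0.75) {
  .assert(is.matrix(X) && nrow(X) == length(y), "X rows must match y")
  p <- ncol(X)
  C <- suppressWarnings(cor(X))
  if (any(!is.finite(C))) {
    .warnf("constant feature(s): undefined correlations treated as 0")
    C[!is.finite(C)] <- 0
  }
  rel <- .class_relevance(X, y)
  hit <- which(upper.tri(C) & abs(C) > r_threshold, arr.ind = TRUE)
  dropped <- logical(p)
  if (nrow(hit)) {
    r <- abs(C)[hit]
    o <- order(-r, hit[, 1], hit[, 2])
    hit <- hit[o, , drop = FALSE]
    for (k in seq_len(nrow(hit))) {
      i <- hit[k, 1]; j <- hit[k, 2]
      if (dropped[i] || dropped[j]) next
      # drop the less relevant member; tie -> keep the earlier column
      dropped[if (rel[j] < rel[i]) j else if (rel[i] < rel[j]) i else j] <- TRUE
    }
  }
  selection_report("pearson", p, colnames(X)[!dropped],
                   list(r_threshold = r_threshold))
}

#' LASSO feature selection
#'
#' Fits an L1-penalized multinomial logistic regression of the class label
#' on the standardized features at a fixed penalty, and keeps every feature
#' with a nonzero coefficient in any class. `alpha = 0` (no penalty) keeps
#' all features.
#'
#' @param X standardized numeric training matrix with column names.
#' @param y integer class labels.
#' @param alpha L1 penalty strength (glmnet `lambda`; default 0.001).
#' @return A [selection_report] with stage `"lasso"`.
#' @export
lasso_select <- function(X, y, alpha = 0.001) {
  .assert(is.matrix(X) && nrow(X) == length(y), "X rows must match y")
  .assert(alpha >= 0, "alpha must be nonnegative")
  if (ncol(X) < 2) {
    return(selection_report("lasso", ncol(X), colnames(X),
                            list(alpha = alpha)))
  }
  # a geometric warm-start path down to the target penalty stabilizes the
  # fit; with well-separated classes the unregularized multinomial loss has
  # no finite optimum, so iterations are capped (with a glmnet warning) and
  # the capped coefficients are used
  lam <- if (alpha > 0) {
    sort(unique(c(exp(seq(log(0.5), log(alpha), length.out = 8)), alpha)),
         decreasing = TRUE)
  } else {
    c(0.5, 0.05, 0.005, 0)
  }
  fit <- glmnet::glmnet(X, factor(y), family = "multinomial", alpha = 1,
                        lambda = lam, standardize = FALSE, maxit = 20000,
                        thresh = 1e-5)
  co <- glmnet::coef.glmnet(fit, s = alpha)
  nz <- Reduce(`|`, lapply(co, function(m) as.matrix(m)[-1, 1] != 0))
  selection_report("lasso", ncol(X), colnames(X)[nz], list(alpha = alpha))
}

# Stratified k-fold assignment, deterministic per seed.
.make_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  .with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Ridge "classifier": multi-response gaussian ridge on the one-hot label
# matrix; prediction is the argmax response. Returns coefficient matrix
# (features x classes) at the given lambda.
.ridge_pad <- function(X) {
  # glmnet requires >= 2 columns; pad single-feature sets with a zero column
  if (ncol(X) == 1) cbind(X, .pad = 0) else X
}

.ridge_fit <- function(X, y, classes, lambda_grid) {
  Y <- vapply(classes, function(cl) as.numeric(y == cl), numeric(length(y)))
  glmnet::glmnet(.ridge_pad(X), Y, family = "mgaussian", alpha = 0,
                 lambda = lambda_grid, standardize = FALSE)
}

.ridge_predict <- function(fit, X, classes, s) {
  pr <- predict(fit, .ridge_pad(X), s = s)[, , 1]
  classes[max.col(matrix(pr, ncol = length(classes)), ties.method = "first")]
}

# K-fold CV accuracy of the ridge classifier for each lambda in the grid.
.ridge_cv_accuracy <- function(X, y, fold, classes, lambda_grid) {
  k <- max(fold)
  acc <- matrix(NA_real_, k, length(lambda_grid))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- .ridge_fit(X[tr, , drop = FALSE], y[tr], classes, lambda_grid)
    for (li in seq_along(lambda_grid)) {
      pred <- .ridge_predict(fit, X[!tr, , drop = FALSE], classes,
                             lambda_grid[li])
      acc[f, li] <- mean(pred == y[!tr])
    }
  }
  colMeans(acc)
}

#' Ridge-based recursive feature elimination with cross-validation
#'
#' Recursive feature elimination (one feature per round) ranked by a ridge
#' classifier's aggregate coefficient magnitude, with stratified k-fold
#' cross-validated accuracy deciding how many features to keep. The ridge
#' classifier regresses the one-hot class matrix on the features and
#' predicts by argmax; its regularization strength is chosen by internal
#' cross-validation over a fixed grid at every step. With fewer than two
#' features the stage is the identity.
#'
#' @param X standardized numeric training matrix with column names.
#' @param y integer class labels; every class must have at least `folds`
#'   members.
#' @param folds number of cross-validation folds (default 5).
#' @param seed fold-assignment seed.
#' @param lambda_grid ridge penalty candidates.
#' @return A [selection_report] with stage `"rfecv"` and a `cv_accuracy`
#'   element in `params` (accuracy per retained-set size).
#' @export
rfecv_select <- function(X, y, folds = 5, seed = 1,
                         lambda_grid = c(100, 10, 1, 0.1, 0.01)) {
  .assert(is.matrix(X) && nrow(X) == length(y), "X rows must match y")
  if (ncol(X) < 2) {
    return(selection_report("rfecv", ncol(X), colnames(X),
                            list(folds = folds)))
  }
  tab <- table(y)
  .assert(all(tab >= folds), "every class needs at least %d members", folds)
  classes <- sort(unique(y))
  fold <- .make_folds(y, folds, seed)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  feats <- colnames(X)
  sets <- list()
  cv_acc <- numeric(0)
  repeat {
    Xc <- X[, feats, drop = FALSE]
    acc <- .ridge_cv_accuracy(Xc, y, fold, classes, lambda_grid)
    sets[[length(feats)]] <- feats
    cv_acc[length(feats)] <- max(acc)
    if (length(feats) == 1) break
    best_lam <- lambda_grid[which.max(acc)]
    fit <- .ridge_fit(Xc, y, classes, lambda_grid)
    co <- glmnet::coef.glmnet(fit, s = best_lam)
    W <- vapply(co, function(m) as.matrix(m)[-1, 1], numeric(length(feats)))
    rank_score <- sqrt(rowSums(matrix(W, nrow = length(feats))^2))
    feats <- feats[-which.min(rank_score)]
  }
  valid <- which(!is.na(cv_acc))
  # highest CV accuracy wins; ties resolved toward fewer features
  top <- max(cv_acc[valid])
  best_size <- min(valid[cv_acc[valid] >= top - 1e-12])
  survivors <- sets[[best_size]]
  selection_report("rfecv", ncol(X), survivors,
                   list(folds = folds, seed = seed,
                        cv_accuracy = cv_acc, best_size = best_size))
}

#' Cascade configuration
#'
#' @param variance_threshold variance cutoff for stage 1 (`NULL` skips).
#' @param r_threshold Pearson cutoff for stage 2 (`NULL` skips).
#' @param lasso_alpha L1 penalty for stage 3 (`NULL` skips).
#' @param rfecv_folds folds for stage 4 (`NULL` skips).
#' @param seed seed for fold assignment.
#' @return A config list for [run_cascade()].
#' @export
cascade_config <- function(variance_threshold = 0.8, r_threshold = 0.75,
                           lasso_alpha = 0.001, rfecv_folds = 5, seed = 42) {
  list(variance_threshold = variance_threshold, r_threshold = r_threshold,
       lasso_alpha = lasso_alpha, rfecv_folds = rfecv_folds, seed = seed)
}

#' Run the four-stage feature-selection cascade
#'
#' Applies, in order: variance threshold on the raw training values;
#' standardization (fit on the training rows) followed by Pearson
#' correlation pruning; LASSO; and ridge-based RFECV. Each stage consumes
#' the previous stage's survivors, so survivor sets are nested by
#' construction. All statistics are computed from the supplied (training)
#' rows only.
#'
#' @param X numeric training feature matrix with column names.
#' @param y integer class labels.
#' @param config a [cascade_config()]; set an entry to `NULL` to skip that
#'   stage.
#' @return Object of class `selection_cascade`: list with `reports` (one
#'   [selection_report] per stage), `survivors` (final feature names),
#'   and `standardizer` (fit on the training rows over the
#'   variance-stage survivors).
#' @export
run_cascade <- function(X, y, config = cascade_config()) {
  .assert(is.matrix(X) && !is.null(colnames(X)), "X must be a named matrix")
  reports <- list()
  feats <- colnames(X)

  rep1 <- if (is.null(config$variance_threshold)) {
    selection_report("variance", length(feats), feats, list(skipped = TRUE))
  } else variance_threshold_select(X, config$variance_threshold)
  reports$variance <- rep1
  feats <- rep1$survivors

  std <- fit_standardizer(X[, feats, drop = FALSE])
  Z <- apply_standardizer(std, X[, feats, drop = FALSE])

  rep2 <- if (is.null(config$r_threshold)) {
    selection_report("pearson", length(feats), feats, list(skipped = TRUE))
  } else correlation_prune(Z, y, config$r_threshold)
  reports$pearson <- rep2
  feats <- rep2$survivors

  rep3 <- if (is.null(config$lasso_alpha)) {
    selection_report("lasso", length(feats), feats, list(skipped = TRUE))
  } else lasso_select(Z[, feats, drop = FALSE], y, config$lasso_alpha)
  reports$lasso <- rep3
  feats <- rep3$survivors

  rep4 <- if (is.null(config$rfecv_folds)) {
    selection_report("rfecv", length(feats), feats, list(skipped = TRUE))
  } else rfecv_select(Z[, feats, drop = FALSE], y,
                      folds = config$rfecv_folds, seed = config$seed)
  reports$rfecv <- rep4
  feats <- rep4$survivors

  structure(list(reports = reports, survivors = feats, standardizer = std,
                 config = config),
            class = "selection_cascade")
}

#' @method print selection_cascade
#' @export
print.selection_cascade <- function(x, ...) {
  cat("<selection_cascade>\n")
  for (r in x$reports) {
    cat(sprintf("  %-8s %5d -> %5d\n", r$stage, r$n_in, r$n_out))
  }
  invisible(x)
}
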