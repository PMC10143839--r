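test_that("splits are exact, disjoint, exhaustive, and reproducible", {
  tab <- tibble::tibble(i = 1:1000, label = rep(0:2, length.out = 1000))
  sp <- split_dataset(tab, split_spec(seed = 7))
  expect_equal(unname(vapply(sp, nrow, integer(1))), c(500, 375, 125))
  ids <- unlist(lapply(sp, `[[`, "i"))
  expect_setequal(ids, tab$i)
  expect_equal(length(ids), length(unique(ids)))
  sp2 <- split_dataset(tab, split_spec(seed = 7))
  expect_identical(lapply(sp, `[[`, "i"), lapply(sp2, `[[`, "i"))
  # a split that would be empty is a contract error
  expect_error(split_dataset(tab[1:3, ], split_spec()), "empty split")
  expect_error(split_spec(0.5, 0.4, 0.2), "sum to 1")
})

test_that("cross-validation separates planted signal and respects seeding", {
  pl <- make_numeric_planted(n = 600, p_noise = 4, seed = 10, margin = 0.5)
  cv <- cross_validate("xgboost", pl$X, pl$y, k = 5, seed = 3,
                       params = list(n_estimators = 100))
  expect_gte(cv$mean, 0.95)
  cv2 <- cross_validate("xgboost", pl$X, pl$y, k = 5, seed = 3,
                        params = list(n_estimators = 100))
  expect_identical(cv$fold_accuracy, cv2$fold_accuracy)
  # leave-one-out at the boundary runs and returns finite values
  small <- make_numeric_planted(n = 12, p_noise = 2, seed = 11)
  cvl <- cross_validate("xgboost", small$X, small$y, k = 12, seed = 1,
                        params = list(n_estimators = 10))
  expect_true(is.finite(cvl$mean) && is.finite(cvl$sd))
})

test_that("label permutation drives accuracy to chance", {
  pl <- make_numeric_planted(n = 240, p_noise = 6, seed = 12)
  set.seed(99)
  accs <- vapply(1:10, function(i) {
    cross_validate("xgboost", pl$X, sample(pl$y), k = 3, seed = i,
                   params = list(n_estimators = 30))$mean
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 3), 3 * max(sd(accs), 0.01))
})

test_that("randomized search samples reproducibly and honors the grid", {
  pl <- make_numeric_planted(n = 200, p_noise = 4, seed = 13)
  single <- list(n_estimators = 40, max_depth = 3)
  res <- randomized_search("xgboost", single, pl$X, pl$y,
                           n_candidates = 1, folds = 3, seed = 1)
  expect_equal(res$best_params, single)

  grid <- list(n_estimators = c(20, 40), max_depth = c(2, 4))
  r1 <- randomized_search("xgboost", grid, pl$X, pl$y, n_candidates = 3,
                          folds = 3, seed = 5)
  r2 <- randomized_search("xgboost", grid, pl$X, pl$y, n_candidates = 3,
                          folds = 3, seed = 5)
  expect_identical(r1$results, r2$results)
  expect_warning(
    randomized_search("xgboost", grid, pl$X, pl$y, n_candidates = 99,
                      folds = 3, seed = 5),
    "capped")
})

test_that("all model families train, predict, and refit deterministically", {
  pl <- make_numeric_planted(n = 240, p_noise = 4, seed = 14)
  Z <- apply_standardizer(fit_standardizer(pl$X), pl$X)
  for (fam in dfi_model_families()) {
    m <- train_final(fam, list(), Z, pl$y, seed = 2)
    pr <- predict(m, Z)
    expect_gte(mean(pr == pl$y), 0.8)
    m2 <- train_final(fam, list(), Z, pl$y, seed = 2)
    expect_identical(predict(m2, Z), pr)
    probs <- predict(m, Z, type = "prob")
    expect_equal(dim(probs), c(nrow(Z), 3))
    expect_equal(unname(rowSums(probs)), rep(1, nrow(Z)), tolerance = 1e-5)
  }
  # training predictions on separable data are near perfect for trees
  m <- train_final("xgboost", list(n_estimators = 80), Z, pl$y, seed = 2)
  expect_gte(mean(predict(m, Z) == pl$y), 0.99)
  # registry mismatch is refused
  bad <- Z[, rev(colnames(Z))]
  expect_error(predict(m, bad), "registry mismatch")
  expect_error(train_final("xgboost", list(), cbind(a = c(1, NA)), 0:1),
               "non-finite")
})

test_that("evaluation reproduces hand-computed one-vs-rest metrics", {
  # class 1: TP = 8, FN = 2, FP = 1, n = 100
  truth <- c(rep(1, 10), rep(0, 45), rep(2, 45))
  pred <- c(rep(1, 8), rep(0, 2), rep(1, 1), rep(0, 44), rep(2, 45))
  rep <- evaluate_predictions(truth, pred)
  row <- rep$per_class[rep$per_class$class == 1, ]
  expect_equal(row$TP, 8); expect_equal(row$FN, 2); expect_equal(row$FP, 1)
  expect_equal(row$recall, 0.8)
  expect_equal(row$precision, 8 / 9)
  expect_equal(row$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))
  expect_equal(row$accuracy, (8 + 89) / 100)
  # confusion conservation
  expect_equal(sum(rep$confusion), 100)
  expect_equal(unname(rowSums(rep$confusion)), c(45, 10, 45))

  perfect <- evaluate_predictions(0:2, 0:2)
  expect_equal(perfect$overall_accuracy, 1)
  expect_true(all(perfect$per_class[, c("accuracy", "recall", "precision",
                                        "f1")] == 1))
  expect_true(all(diag(perfect$confusion) == 1))

  # a class absent from truth and predictions reports 0 with a warning
  expect_warning(deg <- evaluate_predictions(c(0, 0, 1), c(0, 0, 1)),
                 "zero denominator")
  expect_equal(deg$per_class$recall[deg$per_class$class == 2], 0)
  expect_error(evaluate_predictions(0:1, 0:2), "length")
})

test_that("evaluation agrees with a brute-force metric computation", {
  set.seed(15)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    truth <- sample(0:2, n, replace = TRUE)
    pred <- sample(0:2, n, replace = TRUE)
    rep <- suppressWarnings(evaluate_predictions(truth, pred))
    for (cl in 0:2) {
      tp <- 0; fp <- 0; fn <- 0; tn <- 0
      for (j in seq_len(n)) {           # scalar brute force
        if (truth[j] == cl && pred[j] == cl) tp <- tp + 1
        else if (truth[j] != cl && pred[j] == cl) fp <- fp + 1
        else if (truth[j] == cl && pred[j] != cl) fn <- fn + 1
        else tn <- tn + 1
      }
      row <- rep$per_class[rep$per_class$class == cl, ]
      expect_identical(c(row$TP, row$TN, row$FP, row$FN),
                       as.integer(c(tp, tn, fp, fn)))
      expect_equal(row$accuracy, (tp + tn) / n, tolerance = 1e-12)
      rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
      prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
      f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
      expect_equal(row$recall, rec, tolerance = 1e-12)
      expect_equal(row$precision, prec, tolerance = 1e-12)
      expect_equal(row$f1, f1, tolerance = 1e-12)
    }
  }
})
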