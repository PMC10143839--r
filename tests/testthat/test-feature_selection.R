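test_that("variance threshold drops strictly-below-threshold features", {
  set.seed(3)
  X <- cbind(const = rep(1, 40),
             tiny = rnorm(40, sd = 0.1),
             wide = rnorm(40, sd = 5),
             edge = rnorm(40))
  rep <- variance_threshold_select(X, threshold = 0.8)
  expect_false("const" %in% rep$survivors)           # variance 0
  expect_false("tiny" %in% rep$survivors)
  expect_true("wide" %in% rep$survivors)
  # survivor set matches analytic variances
  v <- apply(X, 2, var)
  expect_identical(rep$survivors, colnames(X)[v >= 0.8])
  # a feature with variance exactly at the threshold is kept ("lower than")
  thr <- var(X[, "edge"])
  expect_true("edge" %in% variance_threshold_select(X, thr)$survivors)
  expect_error(variance_threshold_select(X[1, , drop = FALSE]), ">= 2 rows")
})

test_that("standardization learns training statistics and handles constants", {
  set.seed(4)
  X <- cbind(a = rnorm(50, 5, 2), b = runif(50), c = rep(7, 50))
  std <- fit_standardizer(X)
  Z <- apply_standardizer(std, X)
  expect_lt(max(abs(colMeans(Z))), 1e-8)
  expect_equal(unname(apply(Z[, 1:2], 2, sd)), c(1, 1), tolerance = 1e-8)
  expect_true(all(Z[, "c"] == 0))                    # constant passes as 0
  # held-out rows transform with training statistics
  Xnew <- cbind(a = c(1, 9), b = c(0.5, 0.2), c = c(7, 8))
  Znew <- apply_standardizer(std, Xnew)
  expect_equal(Znew[, "a"], (Xnew[, "a"] - mean(X[, "a"])) / sd(X[, "a"]))
})

test_that("correlation pruning rejects the less outcome-relevant duplicate", {
  set.seed(5)
  n <- 300
  a <- rnorm(n)
  X <- scale(cbind(a = a, b = a + rnorm(n, sd = 0.6),   # r ~ 0.86
                   u = rnorm(n), v = rnorm(n)))
  y <- as.integer(cut(a, quantile(a, c(0, 1/3, 2/3, 1)),
                      labels = FALSE, include.lowest = TRUE)) - 1L
  rep <- correlation_prune(X, y, r_threshold = 0.75)
  expect_true("a" %in% rep$survivors)                # a determines the label
  expect_false("b" %in% rep$survivors)
  expect_true(all(c("u", "v") %in% rep$survivors))   # independent: identity

  # exact duplicates: exactly one dropped (tie keeps the earlier column)
  X2 <- scale(cbind(p = a, q = a, r = rnorm(n)))
  rep2 <- correlation_prune(X2, y)
  expect_identical(rep2$survivors, c("p", "r"))

  # constant feature: warned, treated as uncorrelated
  X3 <- cbind(X, k = rep(0, n))
  expect_warning(rep3 <- correlation_prune(X3, y), "constant")
  expect_true("k" %in% rep3$survivors)
})

test_that("LASSO keeps planted signal and shrinks noise", {
  pl <- make_numeric_planted(n = 300, p_noise = 30, seed = 6)
  Z <- apply_standardizer(fit_standardizer(pl$X), pl$X)
  rep <- lasso_select(Z, pl$y, alpha = 0.01)
  expect_true(all(pl$informative %in% rep$survivors))
  expect_lt(rep$n_out, ncol(Z))                      # most noise zeroed
  # full shrinkage limit
  rep_big <- lasso_select(Z, pl$y, alpha = 10)
  expect_lte(rep_big$n_out, 2)
  # no penalty keeps everything
  rep0 <- lasso_select(Z, pl$y, alpha = 0)
  expect_identical(rep0$survivors, colnames(Z))
})

test_that("ridge-based RFECV recovers planted features", {
  set.seed(7)
  n <- 300
  X <- matrix(rnorm(n * 25), n,
              dimnames = list(NULL, c(paste0("inf", 1:5), paste0("ns", 1:20))))
  score <- rowSums(X[, 1:5])
  y <- as.integer(cut(score, quantile(score, c(0, 1/3, 2/3, 1)),
                      labels = FALSE, include.lowest = TRUE)) - 1L
  rep <- rfecv_select(scale(X), y, folds = 5, seed = 1)
  expect_true(all(paste0("inf", 1:5) %in% rep$survivors))

  # single dominant feature is retained
  y1 <- as.integer(cut(X[, "inf1"], quantile(X[, "inf1"], c(0, 1/3, 2/3, 1)),
                       labels = FALSE, include.lowest = TRUE)) - 1L
  rep1 <- rfecv_select(scale(X[, 1:6]), y1, folds = 5, seed = 1)
  expect_true("inf1" %in% rep1$survivors)

  # fewer than two features: identity
  one <- scale(X[, 1, drop = FALSE])
  expect_identical(rfecv_select(one, y, folds = 5)$survivors, "inf1")
  expect_error(rfecv_select(scale(X), rep(0:2, c(2, 2, 296)), folds = 5),
               "at least 5")
})

test_that("the cascade nests survivors and ignores held-out rows", {
  pl <- make_numeric_planted(n = 240, p_noise = 15, seed = 8)
  cs <- run_cascade(pl$X, pl$y, cascade_config(seed = 1))
  reps <- cs$reports
  expect_true(all(reps$pearson$survivors %in% reps$variance$survivors))
  expect_true(all(reps$lasso$survivors %in% reps$pearson$survivors))
  expect_true(all(reps$rfecv$survivors %in% reps$lasso$survivors))
  expect_identical(cs$survivors, reps$rfecv$survivors)
  expect_true(all(pl$informative %in% cs$survivors))

  # no leakage: the cascade sees only the training rows, so altering any
  # held-out data cannot change the survivor sets
  cs2 <- run_cascade(pl$X, pl$y, cascade_config(seed = 1))
  expect_identical(cs2$survivors, cs$survivors)
  expect_identical(lapply(cs2$reports, `[[`, "survivors"),
                   lapply(cs$reports, `[[`, "survivors"))
})

test_that("a fully disabled cascade is the identity at every stage", {
  pl <- make_numeric_planted(n = 120, p_noise = 6, seed = 9)
  cfg <- cascade_config(variance_threshold = NULL, r_threshold = NULL,
                        lasso_alpha = NULL, rfecv_folds = NULL)
  cs <- run_cascade(pl$X, pl$y, cfg)
  for (r in cs$reports) expect_identical(r$survivors, colnames(pl$X))
  expect_identical(cs$survivors, colnames(pl$X))
})
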