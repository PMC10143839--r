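# independent reconstruction of a feature value from its name alone
name_parse_value <- function(name, d, f) {
  if (startsWith(name, "drug.")) return(unname(d[sub("^drug\\.", "", name)]))
  if (startsWith(name, "food.")) return(unname(f[sub("^food\\.", "", name)]))
  if (grepl("*", name, fixed = TRUE)) {
    xy <- strsplit(name, "*", fixed = TRUE)[[1]]
    return(unname(d[xy[1]] * f[xy[2]]))
  }
  xy <- strsplit(name, "+", fixed = TRUE)[[1]]
  unname(d[xy[1]] + f[xy[2]])
}

random_desc <- function(seed) {
  set.seed(seed)
  setNames(rnorm(60), moe_descriptor_registry())
}

test_that("the pair registry has 3780 names and resolves reported signatures", {
  reg <- pair_feature_registry()
  expect_length(reg, 3780)
  expect_false(anyDuplicated(reg) > 0)
  resolved <- resolve_pair_feature(reported_signature_names())
  expect_true(all(resolved %in% reg))
  expect_equal(resolve_pair_feature("MRVSA0"), "drug.MRVSA0")
  expect_error(resolve_pair_feature("NOPE123"), "unknown pair feature")
})

test_that("degenerate descriptor vectors expand as expected", {
  zero <- setNames(rep(0, 60), moe_descriptor_registry())
  expect_true(all(featurize_pair(zero, zero) == 0))
  one <- setNames(rep(1, 60), moe_descriptor_registry())
  v <- featurize_pair(one, one)
  expect_true(all(v[1:120] == 1))                    # singles
  expect_true(all(v[121:180] == 2))                  # sums
  expect_true(all(v[181:3780] == 1))                 # products
})

test_that("every feature value equals its name-parsed recomputation", {
  for (seed in 1:10) {
    d <- random_desc(seed)
    f <- random_desc(seed + 100)
    v <- featurize_pair(d, f)
    expect_length(v, 3780)
    recomputed <- vapply(names(v), name_parse_value, numeric(1), d = d, f = f)
    expect_equal(unname(v), unname(recomputed))
  }
})

test_that("sums are swap-invariant and products transpose under swap", {
  d <- random_desc(1); f <- random_desc(2)
  v <- featurize_pair(d, f)
  w <- featurize_pair(f, d)
  reg <- moe_descriptor_registry()
  sums <- paste0(reg, "+", reg)
  expect_equal(v[sums], w[sums])
  for (pair in list(c("MTPSA", "LabuteASA"), c("slogPVSA0", "MRVSA3"))) {
    expect_equal(unname(v[paste0(pair[1], "*", pair[2])]),
                 unname(w[paste0(pair[2], "*", pair[1])]))
  }
})

test_that("batch featurization matches the single-pair path", {
  reg <- moe_descriptor_registry()
  mk_table <- function(ids, seed0) {
    rows <- lapply(seq_along(ids), function(i) random_desc(seed0 + i))
    out <- tibble::as_tibble(do.call(rbind, rows))
    tibble::add_column(out, id = ids, .before = 1)
  }
  dd <- mk_table(c("d1", "d2"), 10)
  fd <- mk_table(c("f1", "f2"), 20)
  pairs <- tibble::tibble(drug_id = c("d1", "d1", "d2", "d2"),
                          food_id = c("f1", "f2", "f1", "f2"),
                          label = c(0L, 1L, 2L, 1L))
  tab <- featurize_pairs(pairs, dd, fd)
  expect_equal(dim(tab), c(4, 3783))
  for (r in seq_len(4)) {
    d <- setNames(as.numeric(dd[dd$id == pairs$drug_id[r], reg]), reg)
    f <- setNames(as.numeric(fd[fd$id == pairs$food_id[r], reg]), reg)
    expect_equal(setNames(as.numeric(tab[r, pair_feature_registry()]),
                          pair_feature_registry()),
                 featurize_pair(d, f))
  }
  expect_equal(tab$label, pairs$label)

  empty <- featurize_pairs(pairs[0, ], dd, fd)
  expect_equal(nrow(empty), 0)
  expect_true(all(pair_feature_registry() %in% names(empty)))

  bad <- tibble::tibble(drug_id = "dX", food_id = "f1")
  expect_error(featurize_pairs(bad, dd, fd), "dX")
})

test_that("mean-duplicate exclusion removes later equal-mean rows once", {
  reg <- moe_descriptor_registry()
  dd <- tibble::as_tibble(rbind(random_desc(1), random_desc(2)))
  dd <- tibble::add_column(dd, id = c("d1", "d2"), .before = 1)
  fd <- tibble::as_tibble(rbind(random_desc(3)))
  fd <- tibble::add_column(fd, id = "f1", .before = 1)
  pairs <- tibble::tibble(drug_id = c("d1", "d2", "d1"),
                          food_id = c("f1", "f1", "f1"), label = 0L)
  tab <- featurize_pairs(pairs, dd, fd)   # rows 1 and 3 identical
  res <- dedup_by_mean(tab)
  expect_equal(nrow(res$table), 2)
  expect_equal(res$n_removed, 1)
  expect_equal(res$table$drug_id, c("d1", "d2"))
  # idempotent
  res2 <- dedup_by_mean(res$table)
  expect_equal(res2$n_removed, 0)

  # an engineered collision: permuting a row's values preserves its mean
  t2 <- tab[1:2, ]
  feat <- as.numeric(t2[1, pair_feature_registry()])
  t2[2, pair_feature_registry()] <- as.list(rev(feat))
  res3 <- dedup_by_mean(t2)
  expect_equal(nrow(res3$table), 1)
  expect_equal(res3$table$drug_id, "d1")  # first occurrence wins
})
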