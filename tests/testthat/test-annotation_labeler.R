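test_that("text normalization lowercases, strips punctuation, and is idempotent", {
  expect_equal(normalize_text("Take with food."), "take with food")
  expect_equal(normalize_text("AVOID  alcohol"), "avoid alcohol")
  expect_equal(normalize_text("Take (with)  FOOD!"), "take with food")
  n <- normalize_text("Take with, or without; food.")
  expect_equal(normalize_text(n), n)
})

test_that("single annotations classify into the documented classes", {
  expect_equal(classify_annotation("Take with food to reduce nausea.")$label, 1L)
  expect_equal(classify_annotation("Avoid alcohol.")$label, 0L)
  expect_equal(classify_annotation("Take with or without food.")$label, 2L)
  dec <- classify_annotation("Take at the same time every day.")
  expect_equal(dec$status, "ignored")
  expect_true(is.na(dec$label))
  # unmatched sentences fall back to non-significant
  expect_equal(classify_annotation("Food delays gastric emptying.")$label, 2L)
  expect_error(classify_annotation("..."), "empty")
})

test_that("pharmacokinetic conjunction rules fire as specified", {
  # increase + no adverse mention -> positive
  expect_equal(classify_annotation("Food increases bioavailability.")$label, 1L)
  # increase with a negated adverse mention is still positive
  expect_equal(classify_annotation(
    "Food increases the extent of absorption and no adverse effect or toxicity has been observed.")$label, 1L)
  # decrease + adverse -> negative
  expect_equal(classify_annotation(
    "Food reduces the extent of absorption and at least one adverse effect or toxicity has been described.")$label, 0L)
  # decrease alone, no adverse evidence -> not negative
  expect_equal(classify_annotation("Food decreases peak concentrations.")$label, 2L)
})

test_that("the packaged golden annotation set is reproduced exactly", {
  golden <- utils::read.csv(system.file("extdata", "annotation_golden.csv",
                                        package = "dfikit"),
                            colClasses = "character")
  got <- label_drugs(golden[, c("drug_id", "text")])
  expected <- golden[!duplicated(golden$drug_id), c("drug_id", "expected")]
  merged <- merge(got, expected, by = "drug_id")
  want <- rep(NA_integer_, nrow(merged))
  ok <- merged$expected != "ignored"
  want[ok] <- as.integer(merged$expected[ok])
  expect_equal(nrow(merged), length(unique(golden$drug_id)))
  expect_identical(merged$label, want)
})

test_that("drug-level combination follows negative > positive > non-significant", {
  expect_equal(label_drug(c("Take at the same time every day.",
                            "Avoid alcohol."))$label, 0L)
  expect_equal(label_drug(c("Take with food.",
                            "Take with or without food."))$label, 1L)
  expect_equal(label_drug(c("Take with food.", "Avoid alcohol."))$label, 0L)
  expect_equal(label_drug("Take at the same time every day.")$status, "ignored")
  expect_error(label_drug(character(0)), "at least one")
  # order independence up to precedence
  expect_equal(label_drug(c("Avoid alcohol.", "Take with food."))$label,
               label_drug(c("Take with food.", "Avoid alcohol."))$label)
})

test_that("every annotation maps to exactly one class bucket", {
  sentences <- unlist(dfikit:::.annotation_lexicon)
  for (s in sentences) {
    dec <- classify_annotation(s)
    expect_true(dec$status %in% c("negative", "positive", "non_significant",
                                  "ignored"))
    expect_true(is.na(dec$label) || dec$label %in% 0:2)
  }
})

test_that("pairs broadcast drug labels over all foods in stable order", {
  drug_labels <- tibble::tibble(drug_id = c("d1", "d2", "d3"),
                                label = c(0L, NA_integer_, 2L))
  foods <- tibble::tibble(id = c("f1", "f2", "f3"))
  pairs <- build_pairs(drug_labels, foods)
  expect_equal(nrow(pairs), 6)                       # ignored d2 contributes 0
  expect_equal(pairs$drug_id, rep(c("d1", "d3"), each = 3))
  expect_equal(pairs$food_id, rep(c("f1", "f2", "f3"), 2))
  expect_equal(unique(pairs$label[pairs$drug_id == "d1"]), 0L)
  expect_equal(unique(pairs$label[pairs$drug_id == "d3"]), 2L)
  expect_error(build_pairs(drug_labels[2, ], foods), "ignored")

  # labels survive a serialization round trip
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(pairs, path, row.names = FALSE)
  back <- utils::read.csv(path, colClasses = c(label = "integer"))
  expect_equal(back$label, pairs$label)
  expect_equal(back$drug_id, pairs$drug_id)
})
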