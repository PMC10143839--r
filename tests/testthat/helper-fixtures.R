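# Shared fixtures. Anything touching the RDKit bridge is memoised at the
# session level so each expensive object is built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# A small, chemically diverse SMILES panel.
fixture_smiles <- function() {
  c(ethanol = "CCO", benzene = "c1ccccc1", acetic = "CC(=O)O",
    aspirin = "CC(=O)Oc1ccccc1C(=O)O", caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    methane = "C", phenol = "c1ccc(O)cc1", aniline = "Nc1ccccc1",
    pyridine = "c1ccncc1", hexane = "CCCCCC")
}

fixture_descriptors <- function() {
  fixture("descriptors", function() {
    compute_moe_descriptors(unname(fixture_smiles()), id = names(fixture_smiles()))
  })
}

desc_vector <- function(id) {
  tb <- fixture_descriptors()
  v <- as.numeric(tb[tb$id == id, moe_descriptor_registry()])
  setNames(v, moe_descriptor_registry())
}

# Small planted numeric dataset (no chemistry): y from two informative
# columns cut at tertiles, the rest standard normal noise. A positive
# `margin` removes rows near the tertile boundaries, making the classes
# genuinely separable.
make_numeric_planted <- function(n = 240, p_noise = 20, seed = 1,
                                 noise_rate = 0, margin = 0) {
  set.seed(seed)
  X <- cbind(
    inf1 = rnorm(n), inf2 = rnorm(n),
    matrix(rnorm(n * p_noise), n,
           dimnames = list(NULL, paste0("noise", seq_len(p_noise))))
  )
  score <- X[, "inf1"] + X[, "inf2"]
  cuts <- quantile(score, c(1/3, 2/3))
  if (margin > 0) {
    keep <- abs(score - cuts[1]) > margin & abs(score - cuts[2]) > margin
    X <- X[keep, , drop = FALSE]
    score <- score[keep]
  }
  y <- as.integer(cut(score, c(-Inf, cuts, Inf), labels = FALSE)) - 1L
  if (noise_rate > 0) {
    flip <- sample(length(y), round(noise_rate * length(y)))
    y[flip] <- vapply(y[flip], function(l) sample(setdiff(0:2, l), 1), integer(1))
  }
  list(X = X, y = y, informative = c("inf1", "inf2"))
}

# The reference synthetic study (30 drugs x 100 foods, 2% noise, seed 42),
# built once per session and shared across test files.
fixture_default_planted <- function() {
  fixture("default_planted", function()
    generate_planted_dataset(synthetic_config()))
}

# Order-robust map removed_id -> matched_target_id from a filter report.
removal_map <- function(rep) {
  m <- setNames(rep$removed$matched_target_id, rep$removed$removed_id)
  m[order(as.integer(names(m)))]
}

# Random fingerprint sets for filter tests.
make_random_fingerprints <- function(n, n_bits = 2048, density = 0.05,
                                     seed = 1) {
  set.seed(seed)
  fingerprint_set(matrix(runif(n * n_bits) < density, nrow = n))
}

# Independent brute-force greedy sweep (scalar loops only), used as the
# oracle for greedy_dissimilarity_filter.
brute_force_greedy <- function(bits, threshold) {
  n <- nrow(bits)
  removed_by <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!is.na(removed_by[i])) next
    for (j in seq_len(n)) {
      if (j <= i || !is.na(removed_by[j])) next
      a <- bits[i, ]; b <- bits[j, ]
      un <- sum(a | b)
      s <- if (un == 0) 1 else sum(a & b) / un
      if (s >= threshold) removed_by[j] <- i
    }
  }
  list(retained = which(is.na(removed_by)), removed_by = removed_by)
}

# The pair-feature names reported as the optimal signature in this problem
# domain (three shapes: bare singles, same-name sums, cross products).
reported_signature_names <- function() {
  c("MTPSA+MTPSA", "MRVSA9", "MRVSA8", "MRVSA0", "MRVSA2",
    "VSAEstate10+VSAEstate10", "EstateVSA0*LabuteASA", "PEOEVSA12",
    "PEOEVSA10", "PEOEVSA5", "PEOEVSA9", "slogPVSA2", "slogPVSA0",
    "slogPVSA9", "VSAEstate7+VSAEstate7", "EstateVSA7", "EstateVSA2",
    "EstateVSA1*VSAEstate8")
}
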