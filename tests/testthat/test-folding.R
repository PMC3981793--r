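test_that("score_structure sums stacks and loops, open chain scores zero", {
  s <- rna_sequence("s", "GGGAAACCC")
  open <- secondary_structure(NULL, 9)
  expect_equal(score_structure(s, open, 37), 0)
  expect_equal(score_structure(s, open, 80), 0)

  st <- secondary_structure(rbind(c(1, 9), c(2, 8), c(3, 7)), 9)
  # hand-sum from the shipped file: two GC/GC stacks + hairpin loop of 3
  par <- default_energy_params()
  byhand <- 2 * stack_energy("GC/GC", 37, par) +
    loop_energy("hairpin", 3, 37, par)
  expect_equal(score_structure(s, st, 37), byhand, tolerance = 1e-12)
  expect_equal(score_structure(s, st, 37), -1.12, tolerance = 2e-3)

  # additivity: the energy is affine in kelvin because every term is
  expect_equal(score_structure(s, st, 40),
               (score_structure(s, st, 30) + score_structure(s, st, 50)) / 2,
               tolerance = 1e-9)

  bad <- secondary_structure(rbind(c(1, 5)), 9) # G..A, not canonical
  expect_error(score_structure(s, bad, 37), "non-canonical")
})

test_that("enumeration is exhaustive, duplicate-free and guarded", {
  expect_length(enumerate_structures(rna_sequence("a", "AAAA")), 1)

  e <- enumerate_structures(rna_sequence("g", "GAAAC"))
  expect_length(e, 2)
  npairs <- vapply(e, function(s) nrow(s$pairs), 1L)
  expect_setequal(npairs, c(0L, 1L))
  expect_equal(unname(e[[which(npairs == 1)]]$pairs), cbind(1L, 5L))

  for (res in c("GGAAACC", "GCGAAACGCAUAU", "GGGGAAAACCCC")) {
    e <- enumerate_structures(rna_sequence("x", res))
    expect_equal(length(e), count_structures(res))
    expect_false(anyDuplicated(vapply(e, `[[`, "", "dotbracket")) > 0)
  }
  expect_error(enumerate_structures(rna_sequence("x", strrep("A", 21))),
               "length <= 20")
})

test_that("fold_mfe equals the brute-force minimum and scores its own structure", {
  expect_equal(fold_mfe(rna_sequence("a", strrep("A", 8)), 37)$energy, 0)
  expect_equal(fold_mfe(rna_sequence("a", strrep("A", 8)), 37)$structure$dotbracket,
               strrep(".", 8))
  set.seed(501)
  for (k in 1:40) {
    s <- random_rna(sample(8:14, 1))
    tC <- sample(c(20, 37, 55), 1)
    f <- fold_mfe(s, tC)
    expect_equal(f$energy, brute_min_energy(s, tC), tolerance = 1e-9)
    expect_equal(f$energy, score_structure(s, f$structure, tC), tolerance = 1e-12)
    expect_lte(f$energy, 0)
  }
})

test_that("a designed hairpin folds below its melting temperature and opens above", {
  hp <- design_hairpin(thermometer_spec(tm_low = 37, tm_high = 55, seed = 9))
  iso <- rna_sequence("hp", hp$sequence)
  cold <- fold_mfe(iso, hp$predicted_tm - 8)
  hot <- fold_mfe(iso, hp$predicted_tm + 8)
  expect_lt(cold$energy, 0)
  expect_equal(unname(cold$structure$pairs), unname(hp$pairs))
  expect_equal(nrow(hot$structure$pairs), 0)
  expect_equal(hot$energy, 0)
  # verified via score_structure: the designed structure's energy changes
  # sign across the predicted melting temperature
  des <- secondary_structure(hp$pairs, iso$length)
  expect_lt(score_structure(iso, des, hp$predicted_tm - 1), 0)
  expect_gt(score_structure(iso, des, hp$predicted_tm + 1), 0)
})

test_that("partition function matches direct Boltzmann summation", {
  pf <- partition_function(rna_sequence("a", "AAAA"), 37)
  expect_equal(pf$Z, 1)
  expect_equal(max(pf$probs$p), 0)

  set.seed(502)
  for (k in 1:15) {
    s <- random_rna(sample(7:12, 1))
    tC <- sample(c(25, 37, 50), 1)
    oracle <- brute_boltzmann(s, tC)
    pf <- partition_function(s, tC)
    expect_equal(pf$Z, oracle$Z, tolerance = 1e-9)
    expect_lt(max(abs(pf$probs$p - oracle$p)), 1e-9)
    # ensemble consistency with the MFE
    RT <- GAS_CONSTANT * (tC + 273.15)
    expect_gte(pf$Z * (1 + 1e-12), exp(-fold_mfe(s, tC)$energy / RT))
    # per-index probability mass never exceeds one
    tot <- rowSums(pf$probs$p) + colSums(pf$probs$p)
    expect_true(all(tot <= 1 + 1e-9))
  }
})

test_that("GAAAC pair probability reaches its entropic limit at high temperature", {
  # GAAAC has two structures: the open chain and the single pair (1,5).
  # Because loops are purely entropic, E/RT tends to dG37/(R*310.15) as T
  # grows, so the pair probability converges to the entropy-only odds
  # rather than to 1/2.
  par <- default_energy_params()
  q <- exp(-unname(par$hairpin_dG37[["3"]]) / (GAS_CONSTANT * 310.15))
  limit <- q / (1 + q)
  pf <- partition_function(rna_sequence("g", "GAAAC"), 5000)
  expect_equal(pf$probs$p[1, 5], limit, tolerance = 1e-3)
  # and the enthalpic (stack) contribution has washed out relative to 37 C
  p37 <- partition_function(rna_sequence("g", "GAAAC"), 37)$probs$p[1, 5]
  expect_equal(p37, limit, tolerance = 1e-12) # no stack: identical already at 37
})

test_that("centroid thresholds at p > 1/2 and is always a valid structure", {
  mk <- function(p, n) structure(list(n = n, p = p), class = "pair_prob_matrix")
  p <- matrix(0, 9, 9)
  expect_equal(nrow(centroid_structure(mk(p, 9))$pairs), 0)
  p[1, 9] <- 0.9; p[2, 8] <- 0.7; p[3, 7] <- 0.49
  expect_equal(unname(centroid_structure(mk(p, 9))$pairs),
               cbind(c(1L, 2L), c(9L, 8L)))
  set.seed(503)
  for (k in 1:10) {
    s <- random_rna(sample(8:12, 1))
    cen <- centroid_structure(partition_function(s, 30)$probs)
    expect_s3_class(cen, "rna_structure") # constructor enforces invariants
  }
})

test_that("traceback is deterministic", {
  set.seed(504)
  for (k in 1:5) {
    s <- random_rna(25)
    f1 <- fold_mfe(s, 37)
    f2 <- fold_mfe(s, 37)
    expect_identical(f1$structure$dotbracket, f2$structure$dotbracket)
  }
})

test_that("fold() dispatches to builtin modes and external engines by contract", {
  a4 <- rna_sequence("a", "AAAA")
  expect_equal(fold(a4, 37, "mfe")$structure$dotbracket, "....")
  expect_equal(fold(a4, 37, "centroid")$structure$dotbracket, "....")

  register_engine("fixed", function(res, celsius, mode)
    list(dotbracket = strrep(".", nchar(res)), energy = 0))
  f <- fold(rna_sequence("x", "GGGAAACCC"), 37, "mfe", engine = "fixed")
  expect_equal(f$structure$n, 9)
  expect_equal(f$temperature$celsius, 37)

  register_engine("broken", function(res, celsius, mode)
    list(dotbracket = "((((", energy = NA))
  err <- tryCatch(fold(a4, 37, "mfe", engine = "broken"), error = conditionMessage)
  expect_match(err, "unparseable")
  expect_match(err, "\\(\\(\\(\\(") # raw output attached
  expect_error(fold(a4, 37, "mfe", engine = "no-such-engine"), "not registered")
})

test_that("the RNAfold adapter satisfies the engine contract", {
  # full-thermodynamics external engine: only the contract is asserted --
  # a valid structure of the right length, carrying the requested
  # temperature; its structures may disagree with the builtin model
  eng <- rnafold_engine()
  register_engine("rnafold", eng)
  s <- rna_sequence("t", "GGGGAAAACCCC")
  for (mode in c("mfe", "centroid")) {
    f <- fold(s, 42, mode, engine = "rnafold")
    expect_s3_class(f$structure, "rna_structure")
    expect_equal(f$structure$n, 12)
    expect_equal(f$temperature$celsius, 42)
    expect_true(is.finite(f$energy))
  }
})
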