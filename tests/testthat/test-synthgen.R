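test_that("thermometer specs validate their fields", {
  expect_error(thermometer_spec(stem_length = 1), "stem_length")
  expect_error(thermometer_spec(loop_length = 2), "loop_length")
  expect_error(thermometer_spec(tm_low = 50, tm_high = 40), "tm_low")
  expect_silent(thermometer_spec(stem_length = 0)) # control sentinel
})

test_that("designed hairpins melt strictly inside the requested bracket", {
  for (stem in c(8, 10, 12)) {
    spec <- thermometer_spec(stem_length = stem, tm_low = 37, tm_high = 55, seed = 1)
    hp <- design_hairpin(spec)
    expect_gt(hp$predicted_tm, 37)
    expect_lt(hp$predicted_tm, 55)
    expect_equal(nchar(hp$sequence), 2 * stem + spec$loop_length)
    # root located by scanning the designed structure's free energy
    iso <- rna_sequence("h", hp$sequence)
    des <- secondary_structure(hp$pairs, iso$length)
    grid <- seq(spec$tm_low, spec$tm_high, by = 0.5)
    sgn <- sign(vapply(grid, function(tc) score_structure(iso, des, tc), 1))
    flip <- which(diff(sgn) > 0)
    expect_length(flip, 1)
    expect_lt(abs(grid[flip] - hp$predicted_tm), 1)
  }
})

test_that("infeasible melting brackets are refused with the achievable range", {
  # a 2-bp stem cannot melt near 80 C under any composition
  err <- tryCatch(
    design_hairpin(thermometer_spec(stem_length = 2, tm_low = 80, tm_high = 81)),
    error = conditionMessage
  )
  expect_match(err, "achievable range")
})

test_that("records are reproducible from the seed and annotated correctly", {
  spec <- thermometer_spec(seed = 42)
  r1 <- make_record(spec)
  r2 <- make_record(spec)
  expect_identical(r1$sequence$residues, r2$sequence$residues)
  expect_equal(r1$thermometer_interval,
               c(spec$flank5 + 1L, spec$flank5 + 2L * spec$stem_length + spec$loop_length))
  expect_equal(r1$sequence$length,
               spec$flank5 + spec$flank3 + 2L * spec$stem_length + spec$loop_length)
  # the annotated interval really contains the designed stem-loop
  hp <- design_hairpin(spec)
  expect_equal(substr(r1$sequence$residues, r1$thermometer_interval[1],
                      r1$thermometer_interval[2]), hp$sequence)
})

test_that("flanks are low-structure and control records carry no annotation", {
  spec <- thermometer_spec(seed = 7)
  rec <- make_record(spec)
  f5 <- rna_sequence("f5", substr(rec$sequence$residues, 1, spec$flank5))
  expect_gte(fold_mfe(f5, spec$tm_low)$energy, -0.5)

  ctrl <- make_record(thermometer_spec(stem_length = 0, flank5 = 100, flank3 = 100,
                                       seed = 7))
  expect_null(ctrl$thermometer_interval)
  expect_true(is.na(ctrl$predicted_tm))
  expect_equal(ctrl$sequence$length, 200L)
})

test_that("the hairpin's pairs are present cold and absent hot", {
  for (sd in 1:4) {
    rec <- make_record(thermometer_spec(stem_length = 9, seed = sd))
    iv <- rec$thermometer_interval
    win <- rna_sequence("win", substr(rec$sequence$residues, iv[1], iv[2]))
    cold <- fold_mfe(win, rec$spec$tm_low)$structure
    hot <- fold_mfe(win, rec$spec$tm_high)$structure
    expect_gte(bp_distance(cold, hot), rec$spec$stem_length)
  }
})

test_that("closing-pair probability decreases monotonically through the melt", {
  hp <- design_hairpin(thermometer_spec(seed = 1))
  iso <- rna_sequence("h", hp$sequence)
  p_close <- vapply(seq(20, 70, by = 5), function(tc)
    partition_function(iso, tc)$probs$p[1, iso$length], numeric(1))
  expect_true(all(diff(p_close) <= 1e-9))
  expect_gt(p_close[1], 0.9)  # folded well below Tm
  expect_lt(p_close[length(p_close)], 0.1) # molten well above
})

test_that("BED output converts the interval to 0-based half-open", {
  rec <- make_record(thermometer_spec(seed = 3))
  p <- tempfile(fileext = ".bed")
  write_bed(rec, p)
  f <- strsplit(readLines(p), "\t")[[1]]
  expect_equal(as.integer(f[2]), rec$thermometer_interval[1] - 1L)
  expect_equal(as.integer(f[3]), rec$thermometer_interval[2])
  ctrl <- make_record(thermometer_spec(stem_length = 0, seed = 3))
  expect_error(write_bed(ctrl, p), "no thermometer annotation")
})
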