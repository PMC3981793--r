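test_that("scan emits one dot per window in deterministic order", {
  set.seed(601)
  s <- random_rna(48)
  cfg <- suppressWarnings(scan_config(t1 = 30, t2 = 55, wmin = 10, wmax = 16))
  res <- run_scan(s, cfg)
  L <- 48
  expect_equal(nrow(res$dots), sum(pmax(0, L - 10:16 + 1)))
  expect_equal(res$dots$y, res$dots$x + res$dots$window - 1L)
  expect_true(all(res$dots$x >= 1 & res$dots$y <= L))
  # ascending window, then ascending start
  expect_identical(order(res$dots$window, res$dots$x), seq_len(nrow(res$dots)))
  expect_equal(res$max_distance, max(res$dots$distance))
  expect_equal(max(res$dots$intensity), if (res$max_distance > 0) 1 else 0)

  # count formula holds when wmax exceeds the sequence length
  cfg2 <- suppressWarnings(scan_config(t1 = 30, t2 = 55, wmin = 40, wmax = 60))
  res2 <- run_scan(s, cfg2)
  expect_equal(nrow(res2$dots), sum(pmax(0, L - 40:60 + 1)))
})

test_that("equal temperatures give an all-zero scan, with a warning", {
  set.seed(602)
  s <- random_rna(60)
  cfg <- suppressWarnings(scan_config(t1 = 37, t2 = 37, wmin = 20, wmax = 24))
  expect_warning(res <- run_scan(s, cfg), "t1 equals t2")
  expect_true(all(res$dots$distance == 0))
  expect_true(all(res$dots$intensity == 0))
  expect_equal(res$max_distance, 0L)
})

test_that("swapping the two temperatures leaves every distance unchanged", {
  set.seed(603)
  for (k in 1:3) {
    s <- random_rna(45)
    a <- run_scan(s, suppressWarnings(scan_config(t1 = 25, t2 = 55, wmin = 15, wmax = 18)))
    b <- run_scan(s, suppressWarnings(scan_config(t1 = 55, t2 = 25, wmin = 15, wmax = 18)))
    expect_identical(a$dots$distance, b$dots$distance)
  }
})

test_that("intensity normalization is proportional with safe degenerate cases", {
  d <- data.frame(distance = c(0, 3, 6))
  expect_equal(normalize_intensities(d, 6)$intensity, c(0, 0.5, 1))
  expect_equal(normalize_intensities(data.frame(distance = c(0, 0)), 0)$intensity,
               c(0, 0))
  expect_equal(normalize_intensities(data.frame(distance = 7), 7)$intensity, 1)
})

test_that("short sequences error unless the window is clamped", {
  set.seed(604)
  s <- random_rna(30)
  cfg <- scan_config(t1 = 37, t2 = 50) # default 55-80 windows
  expect_error(run_scan(s, cfg), "clamp")
  res <- run_scan(s, cfg, clamp_window = TRUE)
  expect_equal(unique(res$dots$window), 30L)
  expect_equal(nrow(res$dots), 1L)
})

test_that("window-range reliability warning fires outside 50-150", {
  expect_warning(scan_config(wmin = 20, wmax = 80), "less reliable")
  expect_warning(scan_config(wmin = 55, wmax = 160), "less reliable")
  expect_silent(scan_config(wmin = 55, wmax = 80))
  expect_error(scan_config(wmin = 30, wmax = 20), "wmin")
})

test_that("TSV output is deterministic byte for byte", {
  set.seed(605)
  s <- random_rna(70)
  cfg <- suppressWarnings(scan_config(t1 = 30, t2 = 52, wmin = 22, wmax = 26))
  p1 <- tempfile(fileext = ".tsv")
  p2 <- tempfile(fileext = ".tsv")
  write_scan_tsv(run_scan(s, cfg), p1)
  write_scan_tsv(run_scan(s, cfg), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
  expect_equal(readLines(p1)[1], "x\ty\twindow\tdistance\tintensity")
})

test_that("position profile averages intensity over covering windows", {
  # hand-built scan: a single full-intensity dot on [1..5] of a 10-nt scan
  res <- structure(list(
    sequence_id = "toy", sequence_length = 10L,
    config = suppressWarnings(scan_config(t1 = 30, t2 = 50, wmin = 5, wmax = 5)),
    dots = data.frame(x = 1L, y = 5L, window = 5L, distance = 4L, intensity = 1),
    max_distance = 4L
  ), class = "scan_result")
  expect_equal(position_profile(res), c(rep(1, 5), rep(0, 5)))

  set.seed(606)
  s <- random_rna(50)
  zero <- suppressWarnings(
    run_scan(s, suppressWarnings(scan_config(t1 = 37, t2 = 37, wmin = 20, wmax = 22))))
  expect_equal(position_profile(zero), rep(0, 50))
})

test_that("external engines drive the scan through the same contract", {
  # an adapter wrapping the builtin fold must reproduce the builtin scan
  register_engine("builtin-adapter", function(res, celsius, mode) {
    f <- fold_mfe(rna_sequence("w", res), celsius)
    list(dotbracket = f$structure$dotbracket, energy = f$energy)
  })
  set.seed(607)
  s <- random_rna(34)
  cfg_b <- suppressWarnings(scan_config(t1 = 28, t2 = 55, wmin = 12, wmax = 14))
  cfg_e <- suppressWarnings(scan_config(t1 = 28, t2 = 55, wmin = 12, wmax = 14,
                                        engine = "builtin-adapter"))
  a <- run_scan(s, cfg_b)
  b <- run_scan(s, cfg_e)
  expect_identical(a$dots$distance, b$dots$distance)
  expect_identical(a$dots$x, b$dots$x)
})
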