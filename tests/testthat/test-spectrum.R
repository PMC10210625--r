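test_that("spectrum concentrates at the monomer length", {
  sp <- interval_spectrum(strrep("TTAGGG", 500))
  expect_equal(dominant_period(sp), 6L)
  expect_gt(sp$counts[6], 0.9 * sp$total)

  spA <- interval_spectrum(strrep("A", 1000), k = 8)
  expect_equal(which.max(spA$counts), 1L)  # homopolymer: shift-by-one
})

test_that("spectrum equals the brute-force occurrence tally", {
  set.seed(21)
  for (i in 1:12) {
    s <- switch(1 + (i %% 3),
      random_dna(sample(300:2000, 1)),
      strrep(random_primitive_monomer(sample(5:60, 1)), 50),
      paste0(random_dna(500), strrep(random_primitive_monomer(17), 40),
             random_dna(500)))
    sp <- interval_spectrum(s, k = 8, max_lag = 500)
    expect_equal(as.integer(sp$counts),
                 brute_spectrum(s, k = 8, max_lag = 500))
  }
})

test_that("dominant period recovers planted monomer lengths across k", {
  set.seed(22)
  for (len in c(6L, 37L, 127L)) {
    m <- random_primitive_monomer(len, avoid = "TTAGGG")
    if (len == 6L) m <- "TTAGGG"
    arr <- strrep(m, 500)
    for (k in c(6L, 8L, 12L)) {
      sp <- interval_spectrum(arr, k = k)
      expect_equal(dominant_period(sp), len)
    }
  }
})

test_that("dominant period survives 5% per-copy substitution", {
  set.seed(23)
  mono <- list(m = monomer_spec("m",
    seq = random_primitive_monomer(127, avoid = "TTAGGG"),
    mutation_rate = 0.05))
  for (i in 1:5) {
    arr <- build_array(list(kind = "homogeneous", families = "m",
                            copy_counts = list(m = 500L)), mono)
    expect_equal(dominant_period(interval_spectrum(arr$seq)), 127L)
  }
})

test_that("top periods expose harmonics and composite arrays", {
  set.seed(24)
  m <- random_primitive_monomer(50, avoid = "TTAGGG")
  sp <- interval_spectrum(strrep(m, 300), max_lag = 200)
  tp <- top_periods(sp, 2)
  # exact copies: every consecutive spacing is one period, no harmonic
  expect_equal(tp$lag, 50L)
  # substitutions knock out occasional k-mer copies, so skipped-copy
  # harmonics at twice the period surface
  mono <- list(m = monomer_spec("m", seq = m, mutation_rate = 0.05))
  marr <- build_array(list(kind = "homogeneous", families = "m",
                           copy_counts = list(m = 500L)), mono)
  tpm <- top_periods(interval_spectrum(marr$seq, max_lag = 200), 2)
  expect_equal(tpm$lag[1], 50L)
  expect_equal(tpm$lag[2], 100L)  # first harmonic

  # composite short/long array: both periods appear among the top lags
  mono <- default_monomers()
  spec <- list(kind = "AC", families = c("A", "C"),
               copy_counts = list(A = 20L, C = 7L), n_alternations = 50L)
  arr <- build_array(spec, mono)
  spc <- interval_spectrum(arr$seq, max_lag = 1500)
  tp5 <- top_periods(spc, 5)
  expect_true(6L %in% tp5$lag)
  expect_true(127L %in% tp5$lag)

  empty_sp <- structure(list(counts = integer(100), k = 8L,
                             max_lag = 100L, min_kmer_count = 3L,
                             total = 0L), class = "period_spectrum")
  expect_equal(nrow(top_periods(empty_sp, 5)), 0L)
})

test_that("low-signal spectra yield no dominant period", {
  set.seed(25)
  for (i in 1:20) {
    # short iid sequence: total tally stays under the count floor
    sp <- interval_spectrum(random_dna(5000), k = 8)
    expect_true(is.na(dominant_period(sp)))
    # longer iid sequence clears the floor but no lag concentrates
    sp2 <- interval_spectrum(random_dna(20000), k = 8)
    expect_lt(max(sp2$counts) / sp2$total, 0.05)
  }
})

test_that("monomer consensus recovers a rotation of the planted unit", {
  set.seed(26)
  rotations <- function(s) {
    n <- nchar(s)
    vapply(0:(n - 1), function(r) {
      paste0(substr(s, r + 1, n), substr(s, 1, r))
    }, character(1))
  }
  m <- random_primitive_monomer(50, avoid = "TTAGGG")
  cons <- monomer_consensus(strrep(m, 200), 50)
  expect_true(cons %in% rotations(m))

  # doubled period: consensus is a rotation of the doubled unit
  cons2 <- monomer_consensus(strrep(m, 200), 100)
  expect_true(cons2 %in% rotations(paste0(m, m)))

  expect_error(monomer_consensus(strrep(m, 2), 50), "slices")
})

test_that("consensus tolerates 2% per-copy substitution", {
  set.seed(27)
  rotations <- function(s) {
    n <- nchar(s)
    vapply(0:(n - 1), function(r) {
      paste0(substr(s, r + 1, n), substr(s, 1, r))
    }, character(1))
  }
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  for (i in 1:20) {
    m <- random_primitive_monomer(60, avoid = "TTAGGG")
    mono <- list(m = monomer_spec("m", seq = m, mutation_rate = 0.02))
    arr <- build_array(list(kind = "homogeneous", families = "m",
                            copy_counts = list(m = 300L)), mono)
    cons <- monomer_consensus(arr$seq, 60)
    best <- min(vapply(rotations(m), hamming, numeric(1), b = cons))
    expect_lte(best, 2)
  }
})

test_that("telomere array scanning applies the copy threshold exactly", {
  set.seed(28)
  bg <- random_dna(40000)
  plant <- function(s, at, piece) {
    substr(s, at + 1, at + nchar(piece)) <- piece
    s
  }
  s <- plant(bg, 20000, strrep("TTAGGG", 70))
  ta <- telomere_arrays(s)
  expect_equal(nrow(ta), 1L)
  expect_equal(ta$copy_count, 70L)
  expect_equal(ta$kind, "interstitial")
  expect_equal(ta$strand, "+")

  s69 <- plant(bg, 20000, strrep("TTAGGG", 69))
  expect_equal(nrow(telomere_arrays(s69)), 0L)

  sterm <- plant(bg, 0, strrep("TTAGGG", 300))
  tt <- telomere_arrays(sterm)
  expect_equal(tt$kind, "terminal")
  expect_equal(tt$copy_count, 300L)

  srev <- plant(bg, 20000, strrep(revcomp("TTAGGG"), 80))
  tr <- telomere_arrays(srev)
  expect_equal(tr$strand, "-")
  expect_equal(tr$copy_count, 80L)
})
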