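test_that("primitivity testing and monomer drawing work", {
  expect_true(is_primitive("TTAGGG"))
  expect_false(is_primitive("ATAT"))
  expect_false(is_primitive("AAA"))
  set.seed(1)
  m <- random_primitive_monomer(37, avoid = "TTAGGG")
  expect_equal(nchar(m), 37L)
  expect_true(is_primitive(m))
  expect_false(grepl("TTAGGG", m, fixed = TRUE))
  expect_false(grepl("CCCTAA", m, fixed = TRUE))
})

test_that("build_array lengths follow from copy counts by construction", {
  set.seed(2)
  mono <- list(
    A = monomer_spec("A", seq = "TTAGGG"),
    C = monomer_spec("C", seq = random_primitive_monomer(127,
                                                         avoid = "TTAGGG"))
  )
  spec <- list(kind = "AC", families = c("A", "C"),
               copy_counts = list(A = 10L, C = 5L), n_alternations = 3L)
  arr <- build_array(spec, mono)
  expect_equal(arr$length, 3L * (10L * 6L + 5L * 127L))  # 2085
  expect_equal(nchar(arr$seq), 2085L)
  expect_equal(nrow(arr$runs), 6L)
  expect_equal(sum(arr$runs$copies), 45L)

  bspec <- list(kind = "homogeneous", families = "B",
                copy_counts = list(B = 100L))
  monob <- list(B = monomer_spec("B",
    seq = random_primitive_monomer(37, avoid = "TTAGGG")))
  brr <- build_array(bspec, monob)
  expect_equal(brr$length, 3700L)
  expect_equal(nrow(brr$runs), 1L)

  expect_error(build_array(list(kind = "AC", families = c("A", "C"),
                                copy_counts = list(A = 10L, C = 5L),
                                n_alternations = 0L), mono),
               "n_alternations")
})

test_that("orientation blocks reverse-complement whole blocks", {
  set.seed(3)
  monob <- list(B = monomer_spec("B",
    seq = random_primitive_monomer(40, avoid = "TTAGGG")))
  spec <- list(kind = "homogeneous", families = "B",
               copy_counts = list(B = 100L),
               orientation_blocks = list(list(strand = "+", length = 1),
                                         list(strand = "-", length = 1)))
  arr <- build_array(spec, monob)
  expect_equal(nrow(arr$runs), 2L)
  expect_equal(arr$runs$strand, c("+", "-"))
  half1 <- substr(arr$seq, 1, 2000)
  half2 <- substr(arr$seq, 2001, 4000)
  expect_equal(half2, revcomp(strrep(monob$B$seq, 50)))
  expect_equal(half1, strrep(monob$B$seq, 50))
})

test_that("simulated genetic maps integrate the planted rate", {
  set.seed(4)
  m <- simulate_genetic_map(1e7, 0.5, n_markers = 50)
  expect_equal(m$cM, 0.5 * m$bp / 1e6, tolerance = 1e-12)

  hs <- data.frame(start = 0, end = 5e5, fold = 10)
  m2 <- simulate_genetic_map(1e7, 0.5, hotspots = hs, n_markers = 2000)
  # total map length approaches the integral of the rate
  total_expected <- 0.5 * (1e7 + 9 * 5e5) / 1e6
  expect_gt(max(m2$cM), 0.95 * total_expected)

  m3 <- simulate_genetic_map(1e7, 0.5, n_markers = 100, cM_noise_sd = 0.5)
  expect_true(all(diff(m3$cM) >= 0))
  expect_true(all(m3$cM >= 0))

  expect_error(simulate_genetic_map(1e6, 0.5, n_markers = 1), "n_markers")
})

test_that("place_genes flags the requested outliers", {
  set.seed(5)
  g <- place_genes(c(c1 = 1e7, c2 = 1e7), 100, 10)
  expect_equal(sum(g$is_gc_outlier), 10L)
  expect_equal(nrow(g), 100L)
  expect_true(all(g$end - g$start == 2000L))

  g0 <- place_genes(c(c1 = 1e7), 50, 0)
  expect_equal(sum(g0$is_gc_outlier), 0L)

  expect_error(place_genes(c(c1 = 1e7), 10, 11), "exceed")
})

test_that("near-hotspot outliers decay at the Laplace scale", {
  set.seed(6)
  hs <- data.frame(chrom = "c1", start = 4.9e6, end = 5.1e6)
  g <- place_genes(c(c1 = 1e7), 4000, 2000, clustering = "near_hotspots",
                   hotspots = hs, decay_bp = 1e5)
  out <- g[g$is_gc_outlier, ]
  off <- abs((out$start + out$end) / 2 - 5e6)
  # mean |Laplace| offset equals the decay scale
  expect_equal(mean(off), 1e5, tolerance = 0.1)
})

test_that("breakage-fusion-bridge growth appends inverted suffixes", {
  set.seed(7)
  b <- grow_bfb_chromosome(1000, 1, suffix_frac_range = c(1, 1))
  expect_equal(nchar(b$seq), 2000L)
  expect_equal(substr(b$seq, 1001, 2000),
               revcomp(substr(b$seq, 1, 1000)))
  expect_equal(nrow(b$segments), 1L)
  expect_equal(b$segments$orientation, "-")

  expect_error(grow_bfb_chromosome(1000, 0), "n_cycles")

  b3 <- grow_bfb_chromosome(1000, 3)
  expect_lte(nchar(b3$seq), 8000L)
  expect_equal(nrow(b3$segments), 3L)
})

test_that("genome simulation is reproducible from the seed", {
  g1 <- simulate_genome(seed = 99)
  g2 <- simulate_genome(seed = 99)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth$runs, g2$truth$runs)
  expect_identical(g1$truth$markers, g2$truth$markers)
  g3 <- simulate_genome(seed = 100)
  expect_false(identical(as.character(g1$genome),
                         as.character(g3$genome)))
})

test_that("truth intervals match generated sequence content", {
  set.seed(8)
  mono <- default_monomers()
  spec <- list(kind = "AC", families = c("A", "C"),
               copy_counts = list(A = c(10L, 50L), C = c(5L, 10L)),
               n_alternations = 20L)
  arr <- build_array(spec, mono)
  for (i in seq_len(nrow(arr$runs))) {
    r <- arr$runs[i, ]
    piece <- substr(arr$seq, r$start + 1L, r$end)
    unit <- mono[[r$family]]$seq
    expected <- strrep(unit, r$copies)
    if (r$strand == "-") expected <- revcomp(expected)
    expect_identical(piece, expected)
  }
})
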