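make_families <- function(seed = 31) {
  set.seed(seed)
  default_monomers()
}

test_that("monomer mapping tiles exact arrays on both strands", {
  mono <- make_families()
  arr <- strrep(mono$C$seq, 50)
  h <- map_monomers(arr, mono["C"])
  expect_equal(nrow(h), 50L)
  expect_equal(unique(h$strand), "+")
  expect_equal(unique(h$divergence), 0)
  expect_equal(h$start, seq(0L, by = 127L, length.out = 50L))

  hr <- map_monomers(revcomp(arr), mono["C"])
  expect_equal(nrow(hr), 50L)
  expect_equal(unique(hr$strand), "-")
})

test_that("mapped divergence tracks the planted substitution rate", {
  set.seed(32)
  hamming_div <- function(a, b) {
    mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  for (i in 1:20) {
    mono <- list(C = monomer_spec("C",
      seq = random_primitive_monomer(127, avoid = "TTAGGG"),
      mutation_rate = 0.10))
    arr <- build_array(list(kind = "homogeneous", families = "C",
                            copy_counts = list(C = 60L)), mono)
    h <- map_monomers(arr$seq, mono)
    # every copy within the divergence cap is recovered at its anchor
    # (rare binomial-tail copies above the cap are correctly rejected)
    anchors <- seq(0L, by = 127L, length.out = 60L)
    true_div <- vapply(anchors, function(a) {
      hamming_div(substr(arr$seq, a + 1L, a + 127L), mono$C$seq)
    }, numeric(1))
    expect_setequal(h$start, anchors[true_div <= 0.2])
    expect_equal(mean(h$divergence), 0.10, tolerance = 0.25)
    expect_true(all(h$divergence <= 0.2))
  }
})

test_that("hits never overlap and respect the divergence cap", {
  set.seed(33)
  for (i in 1:5) {
    mono <- default_monomers(mutation_rate = 0.05)
    spec <- list(kind = "AC", families = c("A", "C"),
                 copy_counts = list(A = c(10L, 50L), C = c(5L, 10L)),
                 n_alternations = 30L)
    arr <- build_array(spec, mono)
    s <- paste0(random_dna(2000), arr$seq, random_dna(2000))
    h <- map_monomers(s, mono[c("A", "C")], max_divergence = 0.34)
    expect_true(all(h$divergence <= 0.34))
    if (nrow(h) > 1L) {
      expect_true(all(h$start[-1] >= h$end[-nrow(h)]))
    }
  }
})

test_that("segmentation builds AC and homogeneous arrays with thresholds", {
  mono <- make_families()
  spec <- list(kind = "AC", families = c("A", "C"),
               copy_counts = list(A = 20L, C = 7L), n_alternations = 10L)
  arr <- build_array(spec, mono)
  h <- map_monomers(arr$seq, mono[c("A", "C")])
  a <- segment_arrays(h)
  expect_equal(nrow(a), 1L)
  expect_equal(a$array_type, "AC")
  expect_equal(a$copy_count, 270L)

  hb <- map_monomers(strrep(mono$B$seq, 100), mono["B"])
  ab <- segment_arrays(hb)
  expect_equal(ab$array_type, "B")
  expect_equal(ab$copy_count, 100L)

  h5 <- map_monomers(strrep(mono$B$seq, 5), mono["B"])
  expect_equal(nrow(segment_arrays(h5, min_copies = 10L)), 0L)
})

test_that("orientation blocks count strand switches", {
  mono <- make_families()
  plus <- strrep(mono$B$seq, 60)
  h1 <- map_monomers(plus, mono["B"])
  a1 <- segment_arrays(h1)
  ob1 <- orientation_blocks(a1[1, ], h1)
  expect_equal(ob1$n_switches, 0L)
  expect_equal(nrow(ob1$blocks), 1L)

  halves <- paste0(plus, revcomp(plus))
  h2 <- map_monomers(halves, mono["B"])
  a2 <- segment_arrays(h2)
  ob2 <- orientation_blocks(a2[1, ], h2)
  expect_equal(ob2$n_switches, 1L)
  expect_equal(ob2$mean_block_bp, nchar(halves) / 2)

  # planted many-block expansion: switch count is exact, block size close
  set.seed(34)
  nb <- 30L
  spec <- list(kind = "homogeneous", families = "B",
               copy_counts = list(B = 3000L),
               orientation_blocks = lapply(seq_len(nb), function(i) {
                 list(strand = if (i %% 2L) "+" else "-", length = 1)
               }))
  arr <- build_array(spec, mono)
  h3 <- map_monomers(arr$seq, mono["B"])
  a3 <- segment_arrays(h3)
  ob3 <- orientation_blocks(a3[1, ], h3)
  expect_equal(ob3$n_switches, nb - 1L)
  expect_equal(ob3$mean_block_bp, nchar(arr$seq) / nb, tolerance = 0.1)
})

test_that("centromere classification follows the sandwich rule", {
  mk <- function(types) {
    data.frame(chrom = rep("c", length(types)),
               start = seq_along(types) * 1000L,
               end = seq_along(types) * 1000L + 500L,
               array_type = types,
               families = types,
               copy_count = rep(100L, length(types)),
               stringsAsFactors = FALSE)
  }
  ci <- list(chrom = "c", start = 0L, end = 1e6L)
  expect_equal(classify_centromere(ci, mk("AC"))$centromere_class,
               "simple")
  expect_equal(classify_centromere(ci, mk(c("AC", "B")))$centromere_class,
               "asymmetric")
  expect_equal(
    classify_centromere(ci, mk(c("AC", "B", "AC")))$centromere_class,
    "symmetric")
  expect_equal(
    classify_centromere(ci, mk(c("AC", "AC", "B")))$centromere_class,
    "unclassified")
  expect_equal(classify_centromere(ci, mk(character(0)))$centromere_class,
               "unclassified")
  # arrays outside the interval are ignored
  far <- mk(c("AC", "B"))
  far$start <- far$start + 2e6L
  far$end <- far$end + 2e6L
  expect_equal(classify_centromere(ci, far)$centromere_class,
               "unclassified")
})

test_that("expansions are arrays outside the centromere above a size floor", {
  arrays <- data.frame(
    chrom = "c",
    start = c(1e6, 5e6, 2.1e6),
    end = c(2e6, 7.5e6, 2.2e6),
    array_type = c("AC", "B", "B"),
    families = c("A,C", "B", "B"),
    copy_count = c(1000L, 60000L, 100L),
    stringsAsFactors = FALSE)
  ci <- list(chrom = "c", start = 1e6, end = 2e6)
  ex <- detect_expansions(arrays, ci, min_expansion_bp = 1e6)
  expect_equal(nrow(ex), 1L)
  expect_equal(ex$start, 5e6)
  expect_equal(ex$distance_to_centromere, 3e6)
  expect_equal(nrow(detect_expansions(arrays[1, ], ci)), 0L)
})
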