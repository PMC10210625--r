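gene_df <- function(chrom, mid, flag = TRUE) {
  data.frame(chrom = chrom, start = mid - 1000L, end = mid + 1000L,
             gene_id = sprintf("g%03d", seq_along(mid)),
             is_gc_outlier = flag, gc3 = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("nearest-neighbour distance enumerates as expected", {
  g2 <- gene_df("c1", c(1e6L, 3e6L))
  expect_equal(as.numeric(stat_nn_distance(g2)), 2e6)

  g3 <- gene_df("c1", c(0L, 1e6L, 10e6L) + 1000L)
  expect_equal(as.numeric(stat_nn_distance(g3)), (1e6 + 1e6 + 9e6) / 3)

  lonely <- gene_df(c("c1", "c2"), c(1e6L, 1e6L))
  expect_error(stat_nn_distance(lonely), "companion")

  # singletons are excluded but counted
  g4 <- gene_df(c("c1", "c1", "c2"), c(1e6L, 3e6L, 5e6L))
  r <- stat_nn_distance(g4)
  expect_equal(attr(r, "n_used"), 2L)
  expect_equal(as.numeric(r), 2e6)
})

test_that("feature distance is zero inside and excludes bare chromosomes", {
  feats <- data.frame(chrom = "c1", start = 6e6, end = 8e6)
  inside <- gene_df("c1", 7e6L)
  expect_equal(as.numeric(stat_feature_distance(inside, feats)), 0)

  away <- gene_df("c1", 5e6L)
  expect_equal(as.numeric(stat_feature_distance(away, feats)), 1e6)

  mixed <- gene_df(c("c1", "c2"), c(5e6L, 1e6L))
  r <- stat_feature_distance(mixed, feats)
  expect_equal(as.numeric(r), 1e6)
  expect_equal(attr(r, "n_used"), 1L)

  only_bare <- gene_df("c2", 1e6L)
  expect_error(stat_feature_distance(only_bare, feats), "feature-free")
})

test_that("arm position runs from centromere edge to telomere end", {
  cen <- data.frame(chrom = "c1", start = 4e6, end = 6e6)
  len <- c(c1 = 10e6)
  at_end <- gene_df("c1", 10e6L - 1000L)
  expect_equal(as.numeric(stat_arm_position(at_end, cen, len)), 100,
               tolerance = 1e-3)
  near_cen <- gene_df("c1", 6e6L + 2000L)
  expect_lt(as.numeric(stat_arm_position(near_cen, cen, len)), 1)
  inside <- gene_df("c1", c(5e6L, 8e6L))
  r <- stat_arm_position(inside, cen, len)
  expect_equal(attr(r, "n_used"), 1L)
  expect_error(stat_arm_position(gene_df("cX", 1e6L), cen, len),
               "cX")
})

test_that("uniform genes average 50% arm position", {
  set.seed(51)
  len <- c(c1 = 2e7)
  cen <- data.frame(chrom = "c1", start = 9e6, end = 11e6)
  mids <- as.integer(runif(10000, 1000, 2e7 - 1000))
  g <- gene_df("c1", mids)
  r <- stat_arm_position(g, cen, len)
  se <- 100 / sqrt(12) / sqrt(attr(r, "n_used"))
  expect_lt(abs(as.numeric(r) - 50), 2 * se + 0.5)
})

test_that("permutation p-values respect the pseudocount floor", {
  set.seed(52)
  # observed beats every null draw: p is exactly 1/(n_perm + 1)
  feats <- data.frame(chrom = "c1", start = 5e6, end = 5.1e6)
  g <- gene_df("c1", as.integer(runif(200, 1e5, 1e7)), flag = FALSE)
  g$is_gc_outlier[1:10] <- TRUE
  g$start[1:10] <- as.integer(5.02e6 + (1:10) * 100)
  g$end[1:10] <- g$start[1:10] + 2000L
  r <- permutation_test("feature_distance", g, features = feats,
                        n_perm = 999, seed = 7)
  expect_equal(r$p_value, 1 / 1000)
  expect_gte(r$p_value, 1 / (r$n_perm + 1))
  expect_equal(r$direction, "less")
  expect_equal(r$n_genes_used, 10L)
})

test_that("permutation results are invariant to gene order", {
  set.seed(53)
  feats <- data.frame(chrom = "c1", start = c(2e6, 7e6),
                      end = c(2.3e6, 7.3e6))
  g <- gene_df("c1", as.integer(runif(100, 1e5, 1e7)), flag = FALSE)
  g$is_gc_outlier[sample.int(100, 15)] <- TRUE
  r1 <- permutation_test("feature_distance", g, features = feats,
                         n_perm = 200, seed = 9)
  g2 <- g[sample.int(nrow(g)), ]
  r2 <- permutation_test("feature_distance", g2, features = feats,
                         n_perm = 200, seed = 9)
  expect_equal(r1$observed, r2$observed)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("null draws of the outlier set give calibrated p-values", {
  set.seed(54)
  feats <- data.frame(chrom = "c1", start = c(2e6, 7e6),
                      end = c(2.3e6, 7.3e6))
  g <- gene_df("c1", as.integer(runif(300, 1e5, 1e7)), flag = FALSE)
  ps <- replicate(60, {
    gg <- g
    gg$is_gc_outlier[sample.int(300, 30)] <- TRUE
    permutation_test("feature_distance", gg, features = feats,
                     n_perm = 200, seed = sample.int(1e6, 1))$p_value
  })
  # roughly uniform: no mass collapse at either end
  expect_gt(mean(ps <= 0.5), 0.25)
  expect_lt(mean(ps <= 0.05), 0.25)
})
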