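gene_midpoints <- function(genes) (genes$start + genes$end) / 2

#' Mean nearest-neighbour distance within a gene subset
#'
#' Mean over subset genes of the distance from each gene's midpoint to the
#' nearest other subset gene's midpoint on the same chromosome. Genes that
#' are alone on their chromosome are excluded from the mean (their count is
#' available via `attr(, "n_used")`).
#'
#' @param gene_subset Gene data.frame (`chrom`, `start`, `end`).
#' @return Mean distance in bp, with attribute `n_used`.
#' @export
stat_nn_distance <- function(gene_subset) {
  mids <- gene_midpoints(gene_subset)
  sp <- split(mids, gene_subset$chrom)
  dists <- unlist(lapply(sp, function(v) {
    if (length(v) < 2L) return(NULL)
    v <- sort(v)
    gap <- diff(v)
    pmin(c(Inf, gap), c(gap, Inf))
  }), use.names = FALSE)
  if (is.null(dists) || length(dists) == 0L) {
    stop("no gene has a same-chromosome companion")
  }
  structure(mean(dists), n_used = length(dists))
}

# distance from each gene midpoint to the nearest feature interval on the
# same chromosome; NA when the chromosome carries no feature
feature_distances <- function(genes, features) {
  mids <- gene_midpoints(genes)
  out <- rep(NA_real_, nrow(genes))
  for (cc in unique(genes$chrom)) {
    f <- features[features$chrom == cc, , drop = FALSE]
    gi <- which(genes$chrom == cc)
    if (nrow(f) == 0L || length(gi) == 0L) next
    d <- vapply(mids[gi], function(m) {
      inside <- any(m >= f$start & m < f$end)
      if (inside) 0 else min(pmax(f$start - m, 0) + pmax(m - f$end, 0))
    }, numeric(1))
    out[gi] <- d
  }
  out
}

#' Mean distance from a gene subset to the nearest feature
#'
#' Features are intervals (hotspots, telomere arrays, ...). A gene whose
#' midpoint lies inside a feature contributes 0. Genes on chromosomes with
#' no feature are excluded and counted in `attr(, "n_used")`.
#'
#' @param gene_subset Gene data.frame.
#' @param features Feature data.frame (`chrom`, `start`, `end`).
#' @return Mean distance in bp, with attribute `n_used`.
#' @export
stat_feature_distance <- function(gene_subset, features) {
  stopifnot(nrow(features) > 0L)
  d <- feature_distances(gene_subset, features)
  used <- !is.na(d)
  if (!any(used)) stop("all genes lie on feature-free chromosomes")
  structure(mean(d[used]), n_used = sum(used))
}

# per-gene arm position (percent toward the telomere); NA inside the
# centromere or when the chromosome has no centromere call / length
arm_positions <- function(genes, centromeres, chrom_lengths,
                          strict = TRUE) {
  mids <- gene_midpoints(genes)
  out <- rep(NA_real_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    cc <- genes$chrom[i]
    ce <- centromeres[centromeres$chrom == cc, , drop = FALSE]
    if (nrow(ce) == 0L || is.na(chrom_lengths[cc])) {
      if (strict) stop("no centromere call for chromosome ", cc)
      next
    }
    m <- mids[i]
    if (m >= ce$start[1] && m < ce$end[1]) next  # inside the centromere
    if (m < ce$start[1]) {
      arm <- ce$start[1]
      if (arm <= 0) next
      out[i] <- 100 * (ce$start[1] - m) / arm
    } else {
      arm <- chrom_lengths[[cc]] - ce$end[1]
      if (arm <= 0) next
      out[i] <- 100 * (m - ce$end[1]) / arm
    }
  }
  out
}

#' Mean arm position of a gene subset
#'
#' Per gene: the position of its midpoint along its chromosome arm,
#' measured from the centromere edge (0%) toward the telomere end (100%).
#' Genes whose midpoint lies inside the centromere are excluded.
#' Uniformly placed genes average 50%; a subset shifted toward arm ends
#' scores above that.
#'
#' @param gene_subset Gene data.frame.
#' @param centromere_calls data.frame (`chrom`, `start`, `end`) with one
#'   row per chromosome bearing subset genes.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return Mean arm position in percent, with attribute `n_used`.
#' @export
stat_arm_position <- function(gene_subset, centromere_calls,
                              chrom_lengths) {
  p <- arm_positions(gene_subset, centromere_calls, chrom_lengths)
  used <- !is.na(p)
  if (!any(used)) stop("no usable genes for arm-position statistic")
  structure(mean(p[used]), n_used = sum(used))
}

#' Permutation test for the spatial distribution of a flagged gene subset
#'
#' Draws `n_perm` random subsets of the same size as the flagged subset
#' (without replacement from the full gene universe), recomputes the
#' statistic per draw with identical exclusion rules, and reports the
#' one-sided p-value with the add-one pseudocount:
#' p = (1 + #\{null at least as extreme\}) / (n_perm + 1).
#'
#' @param stat_name `"nn_distance"`, `"feature_distance"` or
#'   `"arm_position"`.
#' @param genes Gene universe data.frame with an `is_gc_outlier` column
#'   marking the observed subset.
#' @param features Feature intervals (required for `"feature_distance"`).
#' @param centromeres,chrom_lengths Required for `"arm_position"`.
#' @param n_perm Number of permutations.
#' @param direction `"less"` (subset closer / smaller than null) or
#'   `"greater"`; defaults to the statistic's natural alternative (`less`
#'   for distances, `greater` for arm position).
#' @param seed RNG seed recorded in the result.
#' @param keep_null Return the null sample for plotting.
#' @return List of class `permutation_result`: `statistic_name`,
#'   `observed`, `null_mean`, `null_sd`, `p_value`, `n_perm`, `direction`,
#'   `seed`, `n_genes_used` (and `null` when `keep_null`).
#' @export
permutation_test <- function(stat_name = c("nn_distance",
                                           "feature_distance",
                                           "arm_position"),
                             genes, features = NULL, centromeres = NULL,
                             chrom_lengths = NULL, n_perm = 1e6,
                             direction = NULL, seed = 1L,
                             keep_null = FALSE) {
  stat_name <- match.arg(stat_name)
  if (is.null(direction)) {
    direction <- if (stat_name == "arm_position") "greater" else "less"
  }
  direction <- match.arg(direction, c("less", "greater"))
  # canonical gene order makes the draws (and hence the p-value)
  # independent of the input row order
  genes <- if ("gene_id" %in% names(genes)) {
    genes[order(genes$gene_id), , drop = FALSE]
  } else {
    genes[order(genes$chrom, genes$start, genes$end), , drop = FALSE]
  }
  subset_idx <- which(genes$is_gc_outlier)
  m <- length(subset_idx)
  N <- nrow(genes)
  stopifnot(m >= 1L, m <= N)
  set.seed(seed)

  if (stat_name == "nn_distance") {
    chrom_f <- factor(genes$chrom)
    mids <- gene_midpoints(genes)
    eval_stat <- function(idx) {
      sp <- split(mids[idx], chrom_f[idx])
      dists <- unlist(lapply(sp, function(v) {
        if (length(v) < 2L) return(NULL)
        v <- sort(v)
        gap <- diff(v)
        pmin(c(Inf, gap), c(gap, Inf))
      }), use.names = FALSE)
      if (is.null(dists) || length(dists) == 0L) {
        return(c(NA_real_, 0))
      }
      c(mean(dists), length(dists))
    }
  } else if (stat_name == "feature_distance") {
    if (is.null(features) || nrow(features) == 0L) {
      stop("feature_distance requires features")
    }
    pre <- feature_distances(genes, features)
    eval_stat <- function(idx) {
      v <- pre[idx]
      used <- !is.na(v)
      if (!any(used)) return(c(NA_real_, 0))
      c(mean(v[used]), sum(used))
    }
  } else {
    if (is.null(centromeres) || is.null(chrom_lengths)) {
      stop("arm_position requires centromeres and chrom_lengths")
    }
    pre <- arm_positions(genes, centromeres, chrom_lengths,
                         strict = FALSE)
    eval_stat <- function(idx) {
      v <- pre[idx]
      used <- !is.na(v)
      if (!any(used)) return(c(NA_real_, 0))
      c(mean(v[used]), sum(used))
    }
  }

  obs <- eval_stat(subset_idx)
  if (is.na(obs[1])) stop("observed statistic is undefined for the subset")

  null_vals <- numeric(n_perm)
  n_failed <- 0L
  for (i in seq_len(n_perm)) {
    r <- eval_stat(sample.int(N, m))
    if (is.na(r[1])) n_failed <- n_failed + 1L
    null_vals[i] <- r[1]
  }
  if (n_failed > 0.01 * n_perm) {
    stop(sprintf(
      "statistic undefined on %d of %d permutation draws (> 1%%)",
      n_failed, n_perm))
  }
  ok <- !is.na(null_vals)
  extreme <- if (direction == "less") {
    sum(null_vals[ok] <= obs[1])
  } else {
    sum(null_vals[ok] >= obs[1])
  }
  res <- list(
    statistic_name = stat_name,
    observed = obs[1],
    null_mean = mean(null_vals[ok]),
    null_sd = stats::sd(null_vals[ok]),
    p_value = (1 + extreme) / (n_perm + 1),
    n_perm = as.integer(n_perm),
    direction = direction,
    seed = as.integer(seed),
    n_genes_used = as.integer(obs[2])
  )
  if (keep_null) res$null <- null_vals
  structure(res, class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %s: observed %.4g, null %.4g +/- %.3g, p = %.3g (%s, %d perms, seed %d, n_used %d)\n",
    x$statistic_name, x$observed, x$null_mean, x$null_sd, x$p_value,
    x$direction, x$n_perm, x$seed, x$n_genes_used))
  invisible(x)
}
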