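# window grid shared by all tracks: starts spaced step_bp apart; windows
# are [start, start + window_bp) clipped to the chromosome; at most one
# trailing truncated window is emitted (and flagged)
window_grid <- function(chrom_length, window_bp, step_bp) {
  stopifnot(window_bp >= 1, step_bp >= 1)
  L <- as.integer(chrom_length)
  if (L <= 0) stop("empty chromosome")
  if (window_bp >= L) {
    return(data.frame(start = 0L, end = L, truncated = window_bp > L))
  }
  starts <- seq.int(0L, L - window_bp, by = step_bp)
  ends <- starts + window_bp
  truncated <- rep(FALSE, length(starts))
  last <- starts[length(starts)]
  if (last + window_bp < L && last + step_bp < L) {
    starts <- c(starts, last + step_bp)
    ends <- c(ends, L)
    truncated <- c(truncated, TRUE)
  }
  data.frame(start = as.integer(starts), end = as.integer(ends),
             truncated = truncated)
}

new_window_track <- function(chrom, metric, window_bp, step_bp, grid,
                             values) {
  out <- data.frame(chrom = chrom, start = grid$start, end = grid$end,
                    value = values, truncated = grid$truncated,
                    stringsAsFactors = FALSE)
  attr(out, "metric") <- metric
  attr(out, "window_bp") <- window_bp
  attr(out, "step_bp") <- step_bp
  class(out) <- c("window_track", "data.frame")
  out
}

# per-window base counts via cumulative sums; returns matrix [window, base]
window_base_counts <- function(seq, grid) {
  code <- seq_codes(seq)
  cnt <- matrix(0, nrow = nrow(grid), ncol = 5L)
  for (b in 1:4) {
    cs <- c(0L, cumsum(!is.na(code) & code == b))
    cnt[, b] <- cs[grid$end + 1L] - cs[grid$start + 1L]
  }
  csN <- c(0L, cumsum(is.na(code)))
  cnt[, 5L] <- csN[grid$end + 1L] - csN[grid$start + 1L]
  colnames(cnt) <- c("A", "C", "G", "T", "N")
  cnt
}

#' GC-content sliding-window track
#'
#' Value is (G+C)/(A+C+G+T) per window; windows with more than 50% N are
#' undefined (NA).
#'
#' @param seq Chromosome sequence (character string or
#'   [Biostrings::DNAString]).
#' @param window_bp,step_bp Window and step sizes in bp.
#' @param chrom Chromosome name stored in the track.
#' @return A window track: data.frame with columns `chrom`, `start`, `end`,
#'   `value`, `truncated`, plus `metric`/`window_bp`/`step_bp` attributes.
#' @export
gc_track <- function(seq, window_bp = 1000L, step_bp = 1000L,
                     chrom = "chr") {
  seq <- as.character(seq)
  grid <- window_grid(nchar(seq), window_bp, step_bp)
  cnt <- window_base_counts(seq, grid)
  tot <- rowSums(cnt[, 1:4, drop = FALSE])
  val <- ifelse(tot > 0, (cnt[, "G"] + cnt[, "C"]) / tot, NA_real_)
  width <- grid$end - grid$start
  val[cnt[, "N"] * 2 > width] <- NA_real_
  new_window_track(chrom, "gc", window_bp, step_bp, grid, val)
}

#' Gene-density sliding-window track
#'
#' Value is the number of genes whose midpoint falls inside the half-open
#' window.
#'
#' @param chrom_length Chromosome length in bp.
#' @param genes Gene data.frame (`chrom`, `start`, `end`); only rows
#'   matching `chrom` are counted.
#' @inheritParams gc_track
#' @export
gene_density_track <- function(chrom_length, genes, window_bp = 1e6,
                               step_bp = 1000L, chrom = "chr") {
  grid <- window_grid(chrom_length, window_bp, step_bp)
  g <- if ("chrom" %in% names(genes)) {
    genes[genes$chrom == chrom, , drop = FALSE]
  } else genes
  mids <- sort((g$start + g$end) / 2)
  n_lt <- function(x) findInterval(x - 0.5, mids)  # midpoints < x
  val <- n_lt(grid$end) - n_lt(grid$start)
  new_window_track(chrom, "gene_density", window_bp, step_bp, grid, val)
}

#' Shannon-entropy sliding-window track
#'
#' Value is \eqn{-\sum_b f_b \log_2 f_b} over A/C/G/T with frequencies taken
#' among non-N positions (0 log 0 := 0); windows with more than 50% N are
#' undefined.
#'
#' @inheritParams gc_track
#' @export
entropy_track <- function(seq, window_bp = 10000L, step_bp = 1000L,
                          chrom = "chr") {
  seq <- as.character(seq)
  grid <- window_grid(nchar(seq), window_bp, step_bp)
  cnt <- window_base_counts(seq, grid)
  tot <- rowSums(cnt[, 1:4, drop = FALSE])
  f <- cnt[, 1:4, drop = FALSE] / ifelse(tot > 0, tot, 1)
  h <- -rowSums(ifelse(f > 0, f * log2(f), 0))
  h[tot == 0] <- NA_real_
  width <- grid$end - grid$start
  h[cnt[, "N"] * 2 > width] <- NA_real_
  new_window_track(chrom, "entropy", window_bp, step_bp, grid, h)
}

#' Linguistic-complexity sliding-window track
#'
#' The vocabulary-usage ratio: the number of distinct k-mers observed in
#' the window, summed over k = 1..k_max, divided by the maximum possible,
#' \eqn{\sum_k \min(4^k, L - k + 1)} for window length L. Low values flag
#' repetitive or predictable sequence; satellite arrays score far below
#' i.i.d. background. k-mers containing N are skipped and windows with
#' more than 50% N are undefined.
#'
#' @inheritParams gc_track
#' @param k_max Largest k-mer size; default is the smallest k with
#'   4^k >= window_bp (7 for 10-kb windows), capped at 12.
#' @export
linguistic_complexity_track <- function(seq, window_bp = 10000L,
                                        step_bp = 1000L, k_max = NULL,
                                        chrom = "chr") {
  seq <- as.character(seq)
  if (is.null(k_max)) {
    k_max <- max(1L, ceiling(log(window_bp, base = 4)))
  }
  k_max <- min(as.integer(k_max), 12L)
  grid <- window_grid(nchar(seq), window_bp, step_bp)
  val <- lc_scan_cpp(seq, grid$start, grid$end, k_max)
  tr <- new_window_track(chrom, "linguistic_complexity", window_bp, step_bp,
                         grid, val)
  attr(tr, "k_max") <- k_max
  tr
}
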