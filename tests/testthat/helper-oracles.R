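# Independent brute-force oracles used to validate the scan kernels.
# They share no code with the implementations they check.

# occurrence-list tally of consecutive k-mer spacings
brute_spectrum <- function(seq, k = 8L, max_lag = 3000L, min_count = 3L) {
  n <- nchar(seq)
  stopifnot(n > k)
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  valid <- !grepl("N", kmers, fixed = TRUE)
  occ <- split(which(valid), kmers[valid])
  occ <- occ[lengths(occ) >= min_count]
  tal <- integer(max_lag)
  for (p in occ) {
    g <- diff(p)
    g <- g[g >= 1L & g <= max_lag]
    if (length(g)) {
      tb <- table(g)
      tal[as.integer(names(tb))] <- tal[as.integer(names(tb))] +
        as.integer(tb)
    }
  }
  tal
}

# all maximal matches between character vectors x and y (per diagonal,
# run-length encoded); returns 1-based starts
mem_pairs_raw <- function(x, y, min_len, skip_identity = FALSE) {
  nx <- length(x); ny <- length(y)
  out <- list()
  for (d in (-(nx - 1L)):(ny - 1L)) {
    if (skip_identity && d == 0L) next
    i0 <- max(1L, 1L - d)
    j0 <- i0 + d
    L <- min(nx - i0, ny - j0) + 1L
    if (L < min_len) next
    ii <- i0:(i0 + L - 1L)
    eq <- x[ii] == y[ii + d]
    r <- rle(eq)
    pos <- cumsum(c(0L, r$lengths[-length(r$lengths)])) + 1L
    for (t in seq_along(r$values)) {
      if (r$values[t] && r$lengths[t] >= min_len) {
        out[[length(out) + 1L]] <- c(i = ii[pos[t]], j = ii[pos[t]] + d,
                                     len = r$lengths[t])
      }
    }
  }
  out
}

# brute-force self-MEMs with the same reporting conventions as
# find_self_matches: canonical unordered pairs, forward + inverted
brute_self_mems <- function(seq, min_len) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  rc <- strsplit(revcomp(seq), "", fixed = TRUE)[[1]]
  rows <- list()
  add <- function(a1, a2, b1, b2, strand, len) {
    if (b1 < a1 || (b1 == a1 && b2 < a2)) {
      tmp <- c(a1, a2); a1 <- b1; a2 <- b2; b1 <- tmp[1]; b2 <- tmp[2]
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      a_start = a1, a_end = a2, b_start = b1, b_end = b2,
      strand = strand, length = len, stringsAsFactors = FALSE)
  }
  for (m in mem_pairs_raw(x, x, min_len, skip_identity = TRUE)) {
    add(m["i"] - 1L, m["i"] - 1L + m["len"],
        m["j"] - 1L, m["j"] - 1L + m["len"], "+", m["len"])
  }
  for (m in mem_pairs_raw(x, rc, min_len)) {
    q <- m["j"] - 1L
    add(m["i"] - 1L, m["i"] - 1L + m["len"],
        n - q - m["len"], n - q, "-", m["len"])
  }
  if (length(rows) == 0L) {
    return(data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      strand = character(0), length = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$a_start, out$a_end, out$b_start, out$b_end,
                   out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

expect_same_segments <- function(got, want) {
  cols <- c("a_start", "a_end", "b_start", "b_end", "strand", "length")
  g <- got[, cols]
  w <- want[, cols]
  rownames(g) <- rownames(w) <- NULL
  expect_equal(g, w)
}
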