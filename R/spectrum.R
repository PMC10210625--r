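#' Tandem-repeat periodicity spectrum
#'
#' For every k-mer occurring at least `min_kmer_count` times in the
#' sequence, the distances between consecutive occurrence starts are
#' tallied into a lag histogram. A tandem array with monomer length p
#' repeats every one of its k-mers with spacing p, so the histogram
#' concentrates at the monomer length (and its multiples); i.i.d. sequence
#' spreads thinly over many lags. k-mers containing N are skipped.
#'
#' @param seq Sequence (character or [Biostrings::DNAString]); must be
#'   longer than `k`.
#' @param k k-mer size (default 8).
#' @param max_lag Largest lag tallied.
#' @param min_kmer_count Minimum occurrences for a k-mer to contribute.
#' @return An object of class `period_spectrum`: list with `counts`
#'   (integer vector indexed by lag 1..max_lag), `k`, `max_lag`,
#'   `min_kmer_count`, `total`.
#' @export
interval_spectrum <- function(seq, k = 8L, max_lag = 3000L,
                              min_kmer_count = 3L) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) <= k) stop("sequence shorter than k")
  counts <- spectrum_cpp(seq, as.integer(k), as.integer(max_lag),
                         as.integer(min_kmer_count))
  structure(list(counts = counts, k = as.integer(k),
                 max_lag = as.integer(max_lag),
                 min_kmer_count = as.integer(min_kmer_count),
                 total = sum(counts)),
            class = "period_spectrum")
}

#' @export
print.period_spectrum <- function(x, ...) {
  cat(sprintf("<period_spectrum> k=%d max_lag=%d total=%d\n",
              x$k, x$max_lag, x$total))
  tp <- top_periods(x, 3L)
  if (nrow(tp)) {
    cat("  top lags:",
        paste(sprintf("%d (%d)", tp$lag, tp$count), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Dominant period of a spectrum
#'
#' @param spectrum A `period_spectrum`.
#' @param min_lag Smallest lag considered (default 2: lag 1 is the trivial
#'   homopolymer shift).
#' @param count_floor Minimum total tally for a period to be reported.
#' @return The lag (bp) with the highest count, ties broken toward the
#'   smallest lag, or NA if the spectrum carries too little signal.
#' @export
dominant_period <- function(spectrum, min_lag = 2L, count_floor = 50L) {
  stopifnot(inherits(spectrum, "period_spectrum"))
  if (spectrum$total < count_floor) return(NA_integer_)
  lags <- seq.int(min_lag, spectrum$max_lag)
  cts <- spectrum$counts[lags]
  if (all(cts == 0L)) return(NA_integer_)
  lags[which.max(cts)]
}

#' Highest-count lags of a spectrum
#'
#' Used to detect composite arrays in which two monomer families
#' interleave, so that two lags co-dominate.
#'
#' @inheritParams dominant_period
#' @param n Number of lags to return.
#' @return data.frame with columns `lag`, `count`, descending count then
#'   ascending lag; empty for an empty spectrum.
#' @export
top_periods <- function(spectrum, n, min_lag = 1L) {
  stopifnot(inherits(spectrum, "period_spectrum"))
  lags <- seq.int(min_lag, spectrum$max_lag)
  cts <- spectrum$counts[lags]
  keep <- cts > 0L
  lags <- lags[keep]; cts <- cts[keep]
  if (length(lags) == 0L) {
    return(data.frame(lag = integer(0), count = integer(0)))
  }
  o <- order(-cts, lags)
  utils::head(data.frame(lag = lags[o], count = cts[o]), n)
}

#' Monomer consensus from a tandem array
#'
#' Picks as anchor the most frequent k-mer whose modal consecutive spacing
#' equals the period, cuts the sequence at the anchor occurrences, keeps
#' slices of exactly the period length, and majority-votes each column.
#' The result is one cyclic rotation of the underlying monomer.
#'
#' @param seq Array sequence.
#' @param period Monomer length (from [dominant_period()]).
#' @param k k-mer size used for anchoring.
#' @return Consensus string of length `period`.
#' @export
monomer_consensus <- function(seq, period, k = 8L) {
  seq <- toupper(as.character(seq))
  period <- as.integer(period)
  if (period < 2L) stop("period must be >= 2")
  n <- nchar(seq)
  if (n < 3L * period) stop("fewer than 3 full-length slices available")
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  valid <- !grepl("N", kmers, fixed = TRUE)
  occ <- split(which(valid), kmers[valid])
  occ <- occ[lengths(occ) >= 3L]
  if (length(occ) == 0L) stop("no anchor k-mer with >= 3 occurrences")
  modal_gap <- vapply(occ, function(p) {
    g <- diff(p)
    as.integer(names(sort(table(g), decreasing = TRUE))[1])
  }, integer(1))
  # the anchor's modal spacing must tile the requested period (equal to it,
  # or a proper divisor when a multiple of the true period is requested)
  cand <- occ[modal_gap >= 1L & period %% modal_gap == 0L]
  if (length(cand) == 0L) {
    stop("no anchor k-mer with modal spacing compatible with the period")
  }
  anchor_pos <- cand[[which.max(lengths(cand))]]
  slice_at <- anchor_pos[(anchor_pos + period) %in% anchor_pos &
                           anchor_pos + period - 1L <= n]
  slices <- substring(seq, slice_at, slice_at + period - 1L)
  if (length(slices) < 3L) stop("fewer than 3 full-length slices")
  m <- do.call(rbind, strsplit(slices, "", fixed = TRUE))
  cons <- apply(m, 2L, function(col) {
    tt <- table(col[col != "N"])
    if (length(tt) == 0L) "N" else names(tt)[which.max(tt)]
  })
  paste(cons, collapse = "")
}

#' Scan a chromosome for telomere-motif tandem arrays
#'
#' Maximal runs of exact tandem copies of the motif (and separately of its
#' reverse complement) are located; runs with at least `min_copies` copies
#' are reported. Runs starting or ending within `terminal_margin` of a
#' chromosome end are `terminal`, the rest `interstitial` - relics of
#' ancestral fusions that embed an old chromosome end inside an arm.
#'
#' @param seq Chromosome sequence.
#' @param motif Telomere motif (default TTAGGG).
#' @param min_copies Copy-number threshold (default 70, inclusive).
#' @param terminal_margin Distance from a chromosome end within which a run
#'   counts as terminal.
#' @param chrom Chromosome name for the output.
#' @return data.frame with columns `chrom`, `start`, `end`, `copy_count`,
#'   `strand`, `kind`.
#' @export
telomere_arrays <- function(seq, motif = "TTAGGG", min_copies = 70L,
                            terminal_margin = 10000L, chrom = "chr") {
  stopifnot(nchar(motif) >= 1L)
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  scan_one <- function(m, strand) {
    hits <- gregexpr(paste0("(?:", m, ")+"), seq, perl = TRUE)[[1]]
    if (hits[1] == -1L) {
      return(NULL)
    }
    len <- attr(hits, "match.length")
    copies <- len %/% nchar(m)
    keep <- copies >= min_copies
    if (!any(keep)) return(NULL)
    st <- as.integer(hits[keep]) - 1L
    cp <- copies[keep]
    en <- st + cp * nchar(m)
    data.frame(chrom = chrom, start = st, end = en, copy_count = cp,
               strand = strand, stringsAsFactors = FALSE)
  }
  out <- rbind(scan_one(motif, "+"), scan_one(revcomp(motif), "-"))
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), copy_count = integer(0),
                      strand = character(0), kind = character(0),
                      stringsAsFactors = FALSE))
  }
  out$kind <- ifelse(out$start < terminal_margin |
                       out$end > L - terminal_margin,
                     "terminal", "interstitial")
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
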