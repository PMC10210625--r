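#' Maximal exact matches of a chromosome against itself
#'
#' Finds all maximal exact matches (MEMs) of length at least `min_len`
#' between the sequence and itself (excluding the identity diagonal,
#' reporting each unordered pair once) and between the sequence and its
#' reverse complement, via a suffix-array/LCP structure over the sequence
#' concatenated with its reverse complement. Segments are reported in
#' canonical order (`a` lexicographically before `b`) with exact
#' duplicates removed; on a dot plot the minus-strand segments are the
#' anti-diagonal structure of inverted repeats.
#'
#' Highly periodic sequence (satellite arrays) contains quadratically many
#' MEMs; the `max_segments` guard aborts with advice rather than
#' exhausting memory.
#'
#' @param seq Chromosome sequence (character or [Biostrings::DNAString]).
#' @param min_len Minimum match length (>= 2); the conventional dot-plot
#'   filter is 1000 bp.
#' @param chrom Chromosome name for the output.
#' @param max_segments Abort if the candidate match count exceeds this.
#' @return data.frame with columns `chrom`, `a_start`, `a_end`, `b_start`,
#'   `b_end`, `strand`, `length` (0-based half-open coordinates).
#' @export
find_self_matches <- function(seq, min_len = 1000L, chrom = "chr",
                              max_segments = 2e7) {
  stopifnot(min_len >= 2L)
  seq <- toupper(as.character(seq))
  empty <- data.frame(chrom = character(0), a_start = integer(0),
                      a_end = integer(0), b_start = integer(0),
                      b_end = integer(0), strand = character(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (nchar(seq) < min_len) return(empty)
  r <- sa_mems_cpp(seq, as.integer(min_len), max_segments)
  if (length(r$a_start) == 0L) return(empty)
  out <- data.frame(chrom = chrom, a_start = r$a_start, a_end = r$a_end,
                    b_start = r$b_start, b_end = r$b_end,
                    strand = ifelse(r$strand == 0L, "+", "-"),
                    length = r$length, stringsAsFactors = FALSE)
  # drop the self-pairing of a forward match (identity) and canonicalize
  out <- out[!(out$strand == "+" & out$a_start == out$b_start &
                 out$a_end == out$b_end), , drop = FALSE]
  out <- unique(out)
  out <- out[order(out$a_start, out$a_end, out$b_start, out$b_end,
                   out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of bases present in multiple copies
#'
#' The fraction of sequence positions covered by at least one coordinate
#' range (either side) of a self-alignment segment of length at least
#' `min_len`. Both copies of a duplication count: being "in multiple
#' copies" is a property of positions.
#'
#' @param segments Output of [find_self_matches()] (same or smaller
#'   `min_len`).
#' @param seq_len Chromosome length in bp.
#' @param min_len Length filter applied to segments.
#' @return Fraction in `[0, 1]`.
#' @export
duplicated_fraction <- function(segments, seq_len, min_len = 1000L) {
  s <- segments[segments$length >= min_len, , drop = FALSE]
  if (nrow(s) == 0L) return(0)
  st <- c(s$a_start, s$b_start)
  en <- c(s$a_end, s$b_end)
  red <- merge_intervals(st, en)
  sum(red$end - red$start) / seq_len
}
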