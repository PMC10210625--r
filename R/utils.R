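#' Reverse complement of a DNA string
#'
#' @param x A single character string over the alphabet A, C, G, T, N.
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random i.i.d. DNA sequence
#'
#' Draws bases independently at a given GC content. This is the background
#' model used by the synthetic-genome simulator: it carries no repeat
#' structure, so any periodicity or self-similarity found downstream is
#' attributable to planted features.
#'
#' @param n Length in bp.
#' @param gc GC fraction in `[0,1]`; G and C (and A and T) are equiprobable.
#' @return A character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.42) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  idx <- sample.int(4L, n, replace = TRUE, prob = p)
  intToUtf8(c(65L, 67L, 71L, 84L)[idx])
}

# split a sequence string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# integer base codes: A=1 C=2 G=3 T=4, NA otherwise
seq_codes <- function(x) {
  r <- utf8ToInt(x)
  code <- rep(NA_integer_, length(r))
  code[r == 65L] <- 1L  # A
  code[r == 67L] <- 2L  # C
  code[r == 71L] <- 3L  # G
  code[r == 84L] <- 4L  # T
  code
}

rs_log <- function(fmt, ...) {
  if (isTRUE(getOption("repeatscape.quiet", FALSE))) return(invisible(NULL))
  message(sprintf(paste0("[repeatscape] ", fmt), ...))
}

# merge sorted intervals allowing gaps <= gap; df has start/end (0-based half-open)
merge_intervals <- function(start, end, gap = 0L) {
  if (length(start) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ir <- IRanges::IRanges(start = start + 1L, end = end)  # to 1-based closed
  red <- IRanges::reduce(ir, min.gapwidth = gap + 1L)
  data.frame(start = IRanges::start(red) - 1L, end = IRanges::end(red))
}
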