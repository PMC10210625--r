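#' Marey-map local recombination rates
#'
#' For each window of `w` consecutive markers (stepping one marker at a
#' time), the local recombination rate is the ordinary-least-squares slope
#' of genetic position (cM) on physical position (Mb).
#'
#' @param markers Marker data.frame (`chrom`, `bp`, `cM`) for one
#'   chromosome; duplicated bp positions must already be collapsed (see
#'   [read_markers()]).
#' @param w Markers per window (default 8).
#' @return data.frame with columns `chrom`, `first`, `last` (marker
#'   indices), `start`, `end` (physical span, bp), `slope` (cM/Mb). Empty
#'   (with a logged warning) when fewer than `w` markers are available.
#' @export
marey_rates <- function(markers, w = 8L) {
  stopifnot(w >= 2L)
  m <- markers[order(markers$bp), , drop = FALSE]
  if (length(unique(m$chrom)) > 1L) {
    stop("marey_rates expects markers from a single chromosome")
  }
  n <- nrow(m)
  if (n < w) {
    rs_log("chromosome %s has %d markers (< w = %d); no rate windows",
           m$chrom[1], n, w)
    return(data.frame(chrom = character(0), first = integer(0),
                      last = integer(0), start = integer(0),
                      end = integer(0), slope = numeric(0)))
  }
  if (any(diff(m$bp) <= 0)) stop("marker bp positions must be strictly increasing")
  x <- m$bp / 1e6
  y <- m$cM
  roll <- function(v) {
    cs <- c(0, cumsum(v))
    cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]
  }
  sx <- roll(x); sy <- roll(y); sxx <- roll(x * x); sxy <- roll(x * y)
  slope <- (w * sxy - sx * sy) / (w * sxx - sx^2)
  first <- seq_len(n - w + 1L)
  last <- first + w - 1L
  data.frame(chrom = m$chrom[1], first = first, last = last,
             start = m$bp[first], end = m$bp[last], slope = slope,
             stringsAsFactors = FALSE)
}

#' Genome-average recombination rate
#'
#' Pooled ratio: the summed per-chromosome map length (cM) over the summed
#' per-chromosome marker span (Mb). Chromosomes with fewer than two
#' markers, and any chromosome named in `exclude` (e.g. a non-recombining
#' Y), are omitted.
#'
#' @param markers Marker data.frame across chromosomes.
#' @param exclude Chromosome names to leave out.
#' @return Average rate in cM/Mb.
#' @export
genome_average_rate <- function(markers, exclude = character(0)) {
  m <- markers[!(markers$chrom %in% exclude), , drop = FALSE]
  sp <- split(m, m$chrom)
  sp <- sp[vapply(sp, nrow, integer(1)) >= 2L]
  if (length(sp) == 0L) stop("no chromosome with >= 2 markers")
  tot_cM <- sum(vapply(sp, function(d) max(d$cM) - min(d$cM), numeric(1)))
  tot_Mb <- sum(vapply(sp, function(d) (max(d$bp) - min(d$bp)) / 1e6,
                       numeric(1)))
  tot_cM / tot_Mb
}

#' Call recombination hotspots
#'
#' Rate windows whose slope is at least `fold` times the genome average
#' qualify; overlapping or adjacent qualifying windows merge into one
#' hotspot region whose interval is the union of their physical spans and
#' whose fold is the maximum window slope over the average.
#'
#' @param rate_windows Output of [marey_rates()] (one chromosome).
#' @param avg_rate Genome-average rate from [genome_average_rate()].
#' @param fold Fold threshold (default 5).
#' @return data.frame with columns `chrom`, `start`, `end`, `peak_rate`,
#'   `fold`.
#' @export
call_hotspots <- function(rate_windows, avg_rate, fold = 5.0) {
  stopifnot(avg_rate > 0)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), peak_rate = numeric(0),
                      fold = numeric(0), stringsAsFactors = FALSE)
  if (nrow(rate_windows) == 0L) return(empty)
  q <- rate_windows[!is.na(rate_windows$slope) &
                      rate_windows$slope >= fold * avg_rate, , drop = FALSE]
  if (nrow(q) == 0L) return(empty)
  mg <- merge_intervals(q$start, q$end, gap = 0L)
  out <- do.call(rbind, lapply(seq_len(nrow(mg)), function(i) {
    inwin <- q$start < mg$end[i] & q$end > mg$start[i]
    peak <- max(q$slope[inwin])
    data.frame(chrom = q$chrom[1], start = mg$start[i], end = mg$end[i],
               peak_rate = peak, fold = peak / avg_rate,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
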