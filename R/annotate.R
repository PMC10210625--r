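#' Map monomer-family consensi onto a sequence
#'
#' Greedy non-overlapping tiling. Candidate placements of each consensus
#' (both strands) are anchored wherever the sequence shares an exact k-mer
#' with the doubled consensus, scored by Hamming divergence, and accepted
#' best-score-first; accepted hits then seed tandem extension one monomer
#' length to either side, which rescues mutated copies inside arrays.
#' Remaining gaps stay unannotated.
#'
#' @param seq Sequence to annotate (character or
#'   [Biostrings::DNAString]).
#' @param families Named list of monomer specs ([monomer_spec()]) or a
#'   named character vector of consensi.
#' @param max_divergence Maximum per-copy Hamming divergence (default 0.2;
#'   for very short monomers such as the 6-bp telomere-motif family a
#'   slightly higher value admits two-mismatch copies).
#' @param chrom Chromosome name for the output.
#' @param offset Added to output coordinates (annotate a slice of a
#'   chromosome but report genome coordinates).
#' @return data.frame of hits: `chrom`, `start`, `end`, `family`, `strand`,
#'   `divergence`, sorted by start; hits never overlap.
#' @export
map_monomers <- function(seq, families, max_divergence = 0.2,
                         chrom = "chr", offset = 0L) {
  seq <- toupper(as.character(seq))
  if (is.list(families)) {
    cons <- vapply(families, function(f) f$seq, character(1))
    ids <- vapply(families, function(f) f$family_id, character(1))
  } else {
    cons <- unname(families)
    ids <- names(families)
  }
  stopifnot(length(cons) >= 1L, !is.null(ids), !anyDuplicated(ids))
  h <- map_monomers_cpp(seq, cons, max_divergence)
  out <- data.frame(
    chrom = chrom,
    start = h$start + offset,
    end = h$start + h$length + offset,
    family = ids[h$family],
    strand = ifelse(h$strand == 0L, "+", "-"),
    divergence = h$divergence,
    stringsAsFactors = FALSE
  )
  out[order(out$start), , drop = FALSE]
}

#' Segment monomer hits into repeat arrays
#'
#' Adjacent same-family hits within `gap_bp` merge into runs. Maximal
#' chains of at least `ac_min_alternations` short-family/long-family
#' alternations become one composite `AC` array; remaining runs with at
#' least `min_copies` copies become homogeneous arrays typed by their
#' family (B, C, D, or `homogeneous_other`).
#'
#' @param hits Hit data.frame from [map_monomers()] (one chromosome).
#' @param gap_bp Maximum gap joining hits into a run (and runs into an
#'   array).
#' @param min_copies Minimum copies for a homogeneous array.
#' @param ac_min_alternations Minimum short/long alternations for an AC
#'   array.
#' @return data.frame of arrays: `chrom`, `start`, `end`, `array_type`,
#'   `families`, `copy_count`, `run_ids` (indices into a `runs` attribute
#'   carrying the per-run detail).
#' @export
segment_arrays <- function(hits, gap_bp = 500L, min_copies = 10L,
                           ac_min_alternations = 3L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), array_type = character(0),
                      families = character(0), copy_count = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  hits <- hits[order(hits$start), , drop = FALSE]

  # runs: same family, gap <= gap_bp
  new_run <- c(TRUE, hits$family[-1] != hits$family[-nrow(hits)] |
                 hits$start[-1] - hits$end[-nrow(hits)] > gap_bp)
  run_id <- cumsum(new_run)
  runs <- do.call(rbind, lapply(split(seq_len(nrow(hits)), run_id),
    function(idx) {
      data.frame(chrom = hits$chrom[idx[1]],
                 start = hits$start[idx[1]],
                 end = hits$end[idx[length(idx)]],
                 family = hits$family[idx[1]],
                 copies = length(idx),
                 strand = names(which.max(table(hits$strand[idx]))),
                 first_hit = idx[1], last_hit = idx[length(idx)],
                 stringsAsFactors = FALSE)
    }))
  rownames(runs) <- NULL

  nr <- nrow(runs)
  fam_len <- tapply(hits$end - hits$start, hits$family, stats::median)
  assigned <- rep(FALSE, nr)
  arrays <- list()

  # AC chains: consecutive runs (gap <= gap_bp) alternating two families,
  # one short and one long
  i <- 1L
  while (i <= nr) {
    if (assigned[i]) { i <- i + 1L; next }
    j <- i
    fams <- runs$family[i]
    while (j + 1L <= nr && !assigned[j + 1L] &&
           runs$start[j + 1L] - runs$end[j] <= gap_bp &&
           runs$family[j + 1L] != runs$family[j] &&
           length(unique(c(fams, runs$family[j + 1L]))) <= 2L) {
      j <- j + 1L
      fams <- unique(c(fams, runs$family[j]))
    }
    if (length(fams) == 2L) {
      short_f <- fams[which.min(fam_len[fams])]
      long_f <- fams[which.max(fam_len[fams])]
      # alternation count = number of (short, long) adjacent run pairs
      fseq <- runs$family[i:j]
      n_alt <- sum(fseq[-length(fseq)] == short_f & fseq[-1] == long_f)
      if (n_alt >= ac_min_alternations) {
        arrays[[length(arrays) + 1L]] <- data.frame(
          chrom = runs$chrom[i], start = runs$start[i], end = runs$end[j],
          array_type = "AC",
          families = paste(sort(c(short_f, long_f)), collapse = ","),
          copy_count = sum(runs$copies[i:j]),
          first_run = i, last_run = j, stringsAsFactors = FALSE)
        assigned[i:j] <- TRUE
        i <- j + 1L
        next
      }
    }
    i <- i + 1L
  }

  # homogeneous arrays from leftover runs; merge same-family neighbours
  i <- 1L
  while (i <= nr) {
    if (assigned[i]) { i <- i + 1L; next }
    j <- i
    while (j + 1L <= nr && !assigned[j + 1L] &&
           runs$family[j + 1L] == runs$family[i] &&
           runs$start[j + 1L] - runs$end[j] <= gap_bp) j <- j + 1L
    copies <- sum(runs$copies[i:j])
    if (copies >= min_copies) {
      fam <- runs$family[i]
      arrays[[length(arrays) + 1L]] <- data.frame(
        chrom = runs$chrom[i], start = runs$start[i], end = runs$end[j],
        array_type = if (fam %in% c("B", "C", "D")) fam
                     else "homogeneous_other",
        families = fam, copy_count = copies,
        first_run = i, last_run = j, stringsAsFactors = FALSE)
    }
    assigned[i:j] <- TRUE
    i <- j + 1L
  }

  if (length(arrays) == 0L) return(empty)
  out <- do.call(rbind, arrays)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "runs") <- runs
  out
}

#' Orientation blocks of an array
#'
#' Maximal same-strand runs of constituent monomer hits form blocks;
#' switches between blocks mark internal inversions. For composite AC
#' arrays the orientation signal is taken from the long-family hits, whose
#' length makes strand assignment unambiguous.
#'
#' @param array One row of [segment_arrays()] output.
#' @param hits The hit data.frame the array was built from.
#' @param use_long_family For AC arrays, use only the longer family's hits.
#' @return List: `blocks` (data.frame `strand`, `start`, `end`),
#'   `n_switches`, `mean_block_bp`.
#' @export
orientation_blocks <- function(array, hits, use_long_family = TRUE) {
  h <- hits[hits$start >= array$start & hits$end <= array$end, ,
            drop = FALSE]
  if (nrow(h) == 0L) stop("array has no hits")
  if (use_long_family && array$array_type == "AC") {
    lens <- h$end - h$start
    long_f <- h$family[which.max(lens)]
    h <- h[h$family == long_f, , drop = FALSE]
  }
  r <- rle(h$strand)
  idx_end <- cumsum(r$lengths)
  idx_start <- c(1L, utils::head(idx_end, -1L) + 1L)
  blocks <- data.frame(
    strand = r$values,
    start = h$start[idx_start],
    end = h$end[idx_end],
    stringsAsFactors = FALSE
  )
  # blocks tile the array interval
  blocks$start[1] <- array$start
  blocks$end[nrow(blocks)] <- array$end
  if (nrow(blocks) > 1L) {
    mid <- (blocks$end[-nrow(blocks)] + blocks$start[-1]) %/% 2L
    blocks$end[-nrow(blocks)] <- mid
    blocks$start[-1] <- mid
  }
  list(blocks = blocks,
       n_switches = nrow(blocks) - 1L,
       mean_block_bp = (array$end - array$start) / nrow(blocks))
}

#' Classify a centromere by its array composition
#'
#' One array: `simple`. Two arrays of different types: `asymmetric`.
#' Three arrays whose outer two share a type while the middle differs:
#' `symmetric` (the sandwich arrangement). Anything else is
#' `unclassified`.
#'
#' @param centromere_interval List or one-row data.frame with `chrom`,
#'   `start`, `end`.
#' @param arrays Array data.frame from [segment_arrays()]; rows overlapping
#'   the centromere interval are used, in positional order.
#' @return List of class `centromere_model`: `chrom`, `start`, `end`,
#'   `arrays`, `centromere_class`.
#' @export
classify_centromere <- function(centromere_interval, arrays) {
  ci <- as.list(centromere_interval)
  ov <- arrays[arrays$chrom == ci$chrom & arrays$start < ci$end &
                 arrays$end > ci$start, , drop = FALSE]
  ov <- ov[order(ov$start), , drop = FALSE]
  types <- ov$array_type
  cls <- if (length(types) == 1L) {
    "simple"
  } else if (length(types) == 2L && types[1] != types[2]) {
    "asymmetric"
  } else if (length(types) == 3L && types[1] == types[3] &&
             types[2] != types[1]) {
    "symmetric"
  } else {
    "unclassified"
  }
  structure(list(chrom = ci$chrom, start = ci$start, end = ci$end,
                 arrays = ov, centromere_class = cls),
            class = "centromere_model")
}

#' @export
print.centromere_model <- function(x, ...) {
  cat(sprintf("<centromere_model> %s:%d-%d class=%s [%s]\n", x$chrom,
              x$start, x$end, x$centromere_class,
              paste(x$arrays$array_type, collapse = " | ")))
  invisible(x)
}

#' Flag large satellite arrays outside the centromere
#'
#' Arrays that do not overlap the centromere interval and exceed
#' `min_expansion_bp` are reported with their distance to the centromere -
#' the signature of an intra-arm heterochromatic repeat expansion.
#'
#' @param arrays Array data.frame from [segment_arrays()].
#' @param centromere_interval List with `chrom`, `start`, `end`.
#' @param min_expansion_bp Minimum expansion length.
#' @return Subset of `arrays` with an added `distance_to_centromere`
#'   column.
#' @export
detect_expansions <- function(arrays, centromere_interval,
                              min_expansion_bp = 1e6) {
  ci <- as.list(centromere_interval)
  keep <- arrays$chrom == ci$chrom &
    (arrays$end <= ci$start | arrays$start >= ci$end) &
    (arrays$end - arrays$start) > min_expansion_bp
  out <- arrays[keep, , drop = FALSE]
  if (nrow(out)) {
    out$distance_to_centromere <- ifelse(
      out$end <= ci$start, ci$start - out$end, out$start - ci$end)
  } else {
    out$distance_to_centromere <- numeric(0)
  }
  rownames(out) <- NULL
  out
}
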