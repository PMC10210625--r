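#' Test whether a sequence is a primitive tandem-repeat unit
#'
#' A monomer is primitive when it is not itself a whole number of copies of
#' a shorter unit, so the period of an array built from it is unambiguous.
#'
#' @param s A character string.
#' @return TRUE if no proper divisor of `nchar(s)` is a period of `s`.
#' @export
is_primitive <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(TRUE)
  divs <- which(n %% seq_len(n - 1L) == 0L)
  for (d in divs) {
    if (strrep(substr(s, 1L, d), n %/% d) == s) return(FALSE)
  }
  TRUE
}

# does any k-mer of a occur in b?
shares_kmer <- function(a, b, k = 15L) {
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  km <- unique(substring(a, 1:(nchar(a) - k + 1L), k:nchar(a)))
  any(vapply(km, function(x) grepl(x, b, fixed = TRUE), logical(1)))
}

#' Draw a random primitive monomer
#'
#' Rejection-samples an i.i.d. sequence until it is primitive, does not
#' contain the telomere motif (or its reverse complement), and shares no
#' 15-bp substring with any sequence in `avoid` (or their reverse
#' complements). The constraints keep monomer-family assignment unambiguous
#' when arrays built from several families are re-annotated.
#'
#' @param length Monomer length in bp.
#' @param gc GC content of the draw.
#' @param avoid Character vector of sequences the monomer must not resemble.
#' @param max_tries Rejection budget.
#' @return A character string of the requested length.
#' @export
random_primitive_monomer <- function(length, gc = 0.5, avoid = character(0),
                                     max_tries = 1000L) {
  stopifnot(length >= 1L)
  avoid_all <- c(avoid, vapply(avoid, revcomp, character(1)))
  for (i in seq_len(max_tries)) {
    s <- random_dna(length, gc)
    if (!is_primitive(s)) next
    if (length >= 6L &&
        (grepl("TTAGGG", s, fixed = TRUE) || grepl("CCCTAA", s, fixed = TRUE)))
      next
    clash <- FALSE
    for (a in avoid_all) {
      if (shares_kmer(s, a) || shares_kmer(a, s)) { clash <- TRUE; break }
    }
    if (!clash) return(s)
  }
  stop("could not draw an acceptable primitive monomer in ", max_tries,
       " tries")
}

#' Monomer family specification
#'
#' @param family_id Short family label, e.g. `"A"`.
#' @param seq Monomer sequence; drawn with [random_primitive_monomer()] if
#'   NULL.
#' @param length Required when `seq` is NULL.
#' @param mutation_rate Per-copy, per-base substitution probability in
#'   `[0, 0.3]` applied when arrays are built from this family.
#' @return A list with elements `family_id`, `seq`, `length`,
#'   `mutation_rate`.
#' @export
monomer_spec <- function(family_id, seq = NULL, length = NULL,
                         mutation_rate = 0) {
  if (is.null(seq)) {
    stopifnot(!is.null(length))
    seq <- random_primitive_monomer(length)
  }
  stopifnot(is_primitive(seq), mutation_rate >= 0, mutation_rate <= 0.3)
  list(family_id = family_id, seq = toupper(seq), length = nchar(seq),
       mutation_rate = mutation_rate)
}

#' Default satellite monomer set
#'
#' Four families of the lengths characteristic of gerbil-like centromeric
#' satellites: the 6-bp telomere-motif family A (TTAGGG), plus randomly
#' drawn primitive monomers of 37 bp (B), 127 bp (C) and 1747 bp (D).
#' B, C and D are drawn under the current RNG state with mutual-dissimilarity
#' constraints (see [random_primitive_monomer()]).
#'
#' @param mutation_rate Per-copy substitution rate shared by all families.
#' @return Named list of monomer specs keyed by family id.
#' @export
default_monomers <- function(mutation_rate = 0) {
  a <- monomer_spec("A", seq = "TTAGGG", mutation_rate = mutation_rate)
  b <- monomer_spec("B",
    seq = random_primitive_monomer(37L, avoid = a$seq),
    mutation_rate = mutation_rate)
  c_ <- monomer_spec("C",
    seq = random_primitive_monomer(127L, avoid = c(a$seq, b$seq)),
    mutation_rate = mutation_rate)
  d <- monomer_spec("D",
    seq = random_primitive_monomer(1747L, avoid = c(a$seq, b$seq, c_$seq)),
    mutation_rate = mutation_rate)
  list(A = a, B = b, C = c_, D = d)
}

# substitution-only mutation of a sequence string
mutate_seq <- function(s, rate) {
  if (rate <= 0 || nchar(s) == 0L) return(s)
  ch <- seq_chars(s)
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    }
    s <- paste(ch, collapse = "")
  }
  s
}

#' Build a satellite array from monomer families
#'
#' Two kinds are supported. `"AC"` arrays interleave runs of a short family
#' with runs of a long family for `n_alternations` rounds, with run lengths
#' drawn uniformly from per-family ranges (defaults 10-50 short copies
#' against 5-10 long copies per round). `"homogeneous"` arrays are a single
#' run of one family. Each monomer copy is mutated independently at the
#' family's substitution rate. Orientation blocks are realized by
#' reverse-complementing whole blocks of runs; block boundaries snap to run
#' boundaries so the emitted truth stays exact.
#'
#' @param spec List with elements `kind` (`"AC"` or `"homogeneous"`),
#'   `families` (family ids; exactly two for `"AC"`), `copy_counts` (named
#'   list of `c(min, max)` ranges or single counts per family),
#'   `n_alternations` (AC only), `orientation_blocks` (optional list of
#'   `list(strand, length)`).
#' @param monomers Named list of monomer specs (see [monomer_spec()]).
#' @return List with `seq` (character), `runs` (data.frame with columns
#'   `start`, `end`, `family`, `copies`, `strand`, 0-based half-open, array
#'   local coordinates) and `length`.
#' @export
build_array <- function(spec, monomers) {
  kind <- match.arg(spec$kind, c("AC", "homogeneous"))
  fams <- spec$families
  if (!all(fams %in% names(monomers))) {
    stop("unknown monomer families: ",
         paste(setdiff(fams, names(monomers)), collapse = ", "))
  }
  draw_copies <- function(fam) {
    r <- spec$copy_counts[[fam]]
    if (is.null(r)) stop("no copy_counts for family ", fam)
    if (length(r) == 1L) as.integer(r)
    else sample(seq.int(r[1], r[2]), 1L)
  }
  runs <- list()
  if (kind == "AC") {
    if (length(fams) != 2L) stop("AC arrays reference exactly two families")
    if (is.null(spec$n_alternations) || spec$n_alternations < 1L) {
      stop("n_alternations must be >= 1")
    }
    # short family first in each round
    ord <- fams[order(vapply(fams, function(f) monomers[[f]]$length,
                             numeric(1)))]
    for (i in seq_len(spec$n_alternations)) {
      runs[[length(runs) + 1L]] <- list(family = ord[1],
                                        copies = draw_copies(ord[1]))
      runs[[length(runs) + 1L]] <- list(family = ord[2],
                                        copies = draw_copies(ord[2]))
    }
  } else {
    if (length(fams) != 1L) stop("homogeneous arrays have one family")
    total <- draw_copies(fams[1])
    ob <- spec$orientation_blocks
    if (is.null(ob) || length(ob) <= 1L) {
      runs[[1L]] <- list(family = fams[1], copies = total)
    } else {
      # split the copies into one run per orientation block so block
      # boundaries fall on monomer-copy boundaries
      w <- vapply(ob, function(b) b$length, numeric(1))
      cuts <- round(cumsum(w) / sum(w) * total)
      cuts[length(cuts)] <- total
      per <- diff(c(0, cuts))
      if (any(per < 1)) stop("orientation blocks too small for copy count")
      for (i in seq_along(per)) {
        runs[[length(runs) + 1L]] <- list(family = fams[1],
                                          copies = as.integer(per[i]))
      }
    }
  }

  # realize each run with per-copy mutation
  for (i in seq_along(runs)) {
    m <- monomers[[runs[[i]]$family]]
    s <- strrep(m$seq, runs[[i]]$copies)
    runs[[i]]$seq <- mutate_seq(s, m$mutation_rate)
    runs[[i]]$strand <- "+"
  }

  # orientation blocks: partition runs by cumulative length, flip '-' blocks
  if (!is.null(spec$orientation_blocks) &&
      length(spec$orientation_blocks) > 1L ||
      (length(spec$orientation_blocks) == 1L &&
       spec$orientation_blocks[[1]]$strand == "-")) {
    lens <- vapply(runs, function(r) nchar(r$seq), numeric(1))
    cum <- cumsum(lens)
    total <- sum(lens)
    targets <- cumsum(vapply(spec$orientation_blocks,
                             function(b) b$length, numeric(1)))
    targets <- targets / targets[length(targets)] * total
    # snap block ends to nearest run boundary, keeping them increasing
    ends <- integer(length(targets))
    prev <- 0L
    for (j in seq_along(targets)) {
      if (j == length(targets)) { ends[j] <- length(runs); break }
      cand <- which.min(abs(cum - targets[j]))
      ends[j] <- max(cand, prev + 1L)
      prev <- ends[j]
    }
    new_runs <- list()
    prev <- 0L
    for (j in seq_along(ends)) {
      idx <- (prev + 1L):ends[j]
      prev <- ends[j]
      blk <- runs[idx]
      if (spec$orientation_blocks[[j]]$strand == "-") {
        blk <- rev(blk)
        blk <- lapply(blk, function(r) {
          r$seq <- revcomp(r$seq)
          r$strand <- "-"
          r
        })
      }
      new_runs <- c(new_runs, blk)
    }
    runs <- new_runs
  }

  seqs <- vapply(runs, function(r) r$seq, character(1))
  lens <- nchar(seqs)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  truth <- data.frame(
    start = as.integer(starts),
    end = as.integer(starts + lens),
    family = vapply(runs, function(r) r$family, character(1)),
    copies = vapply(runs, function(r) as.integer(r$copies), integer(1)),
    strand = vapply(runs, function(r) r$strand, character(1)),
    stringsAsFactors = FALSE
  )
  list(seq = paste(seqs, collapse = ""), runs = truth,
       length = sum(lens))
}

#' Simulate a genetic map with planted recombination hotspots
#'
#' Marker physical positions are uniform on the chromosome; genetic
#' positions are the integral of a piecewise-constant recombination rate
#' (base rate times a fold multiplier inside hotspots) plus optional
#' Gaussian noise, sorted afterwards so cM stays monotone non-decreasing.
#'
#' @param chrom_length Chromosome length in bp.
#' @param base_rate_cM_per_Mb Background rate.
#' @param hotspots NULL or data.frame with `start`, `end` (bp) and `fold`
#'   (multiplier >= 1).
#' @param n_markers Number of markers (>= 2).
#' @param cM_noise_sd Standard deviation of the cM noise.
#' @param chrom Chromosome name for the marker table.
#' @return data.frame with columns `chrom`, `bp`, `cM`.
#' @export
simulate_genetic_map <- function(chrom_length, base_rate_cM_per_Mb,
                                 hotspots = NULL, n_markers,
                                 cM_noise_sd = 0, chrom = "chr1") {
  if (n_markers < 2L) stop("n_markers must be >= 2")
  if (!is.null(hotspots) && nrow(hotspots) > 0 && any(hotspots$fold < 1)) {
    stop("hotspot fold multipliers must be >= 1")
  }
  bp <- sort(sample.int(chrom_length, n_markers))
  cm_at <- function(x) {
    v <- x
    if (!is.null(hotspots) && nrow(hotspots) > 0) {
      for (i in seq_len(nrow(hotspots))) {
        ov <- pmax(0, pmin(x, hotspots$end[i]) - hotspots$start[i])
        v <- v + (hotspots$fold[i] - 1) * ov
      }
    }
    base_rate_cM_per_Mb * v / 1e6
  }
  cM <- cm_at(bp)
  if (cM_noise_sd > 0) {
    cM <- sort(cM + stats::rnorm(n_markers, sd = cM_noise_sd))
    cM <- pmax(cM, 0)
  }
  data.frame(chrom = chrom, bp = as.integer(bp), cM = cM,
             stringsAsFactors = FALSE)
}

#' Place genes (and flagged outlier genes) on a genome
#'
#' In `"uniform"` mode all genes are placed uniformly (chromosome chosen
#' proportional to length) and a random subset is flagged as GC outliers;
#' this is the null configuration the permutation test assumes. In
#' `"near_hotspots"` mode the flagged genes' midpoints are planted at the
#' centre of a random hotspot plus a Laplace-distributed offset whose mean
#' absolute value equals `decay_bp`.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_genes Total gene count.
#' @param n_outliers Number of flagged genes (<= n_genes).
#' @param clustering `"uniform"` or `"near_hotspots"`.
#' @param hotspots data.frame (`chrom`, `start`, `end`) required for
#'   `"near_hotspots"`.
#' @param decay_bp Laplace scale of the offsets.
#' @param gene_length Fixed gene length in bp.
#' @return data.frame with columns `chrom`, `start`, `end`, `gene_id`,
#'   `is_gc_outlier`, `gc3`.
#' @export
place_genes <- function(chrom_lengths, n_genes, n_outliers,
                        clustering = c("uniform", "near_hotspots"),
                        hotspots = NULL, decay_bp = 1e5,
                        gene_length = 2000L) {
  clustering <- match.arg(clustering)
  if (n_outliers > n_genes) stop("n_outliers cannot exceed n_genes")
  if (clustering == "near_hotspots" &&
      (is.null(hotspots) || nrow(hotspots) == 0)) {
    stop("near_hotspots clustering requires hotspot truth")
  }
  half <- gene_length %/% 2L
  place_uniform <- function(n) {
    chrom <- sample(names(chrom_lengths), n, replace = TRUE,
                    prob = chrom_lengths)
    mid <- vapply(chrom, function(cc) {
      L <- chrom_lengths[[cc]]
      floor(stats::runif(1, half, L - half))
    }, numeric(1))
    data.frame(chrom = chrom, mid = mid, stringsAsFactors = FALSE)
  }
  if (clustering == "uniform") {
    pos <- place_uniform(n_genes)
    flag <- rep(FALSE, n_genes)
    if (n_outliers > 0) flag[sample.int(n_genes, n_outliers)] <- TRUE
  } else {
    n_bg <- n_genes - n_outliers
    bg <- place_uniform(n_bg)
    hs <- hotspots[sample.int(nrow(hotspots), n_outliers, replace = TRUE), ,
                   drop = FALSE]
    centre <- (hs$start + hs$end) / 2
    lap <- stats::rexp(n_outliers, rate = 1 / decay_bp) *
      sample(c(-1, 1), n_outliers, replace = TRUE)
    mid <- round(centre + lap)
    L <- chrom_lengths[hs$chrom]
    mid <- pmin(pmax(mid, half), L - half)
    out <- data.frame(chrom = hs$chrom, mid = mid, stringsAsFactors = FALSE)
    pos <- rbind(bg, out)
    flag <- c(rep(FALSE, n_bg), rep(TRUE, n_outliers))
  }
  data.frame(
    chrom = pos$chrom,
    start = as.integer(pos$mid - half),
    end = as.integer(pos$mid - half + gene_length),
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    is_gc_outlier = flag,
    gc3 = NA_real_,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Grow a chromosome by breakage-fusion-bridge cycles
#'
#' Each cycle appends the reverse complement of a random-length suffix of
#' the current sequence (suffix fraction uniform in `suffix_frac_range`),
#' optionally applying substitutions to the appended copy. This emulates
#' the inverted-duplication growth that produces chromosomes whose bases
#' are almost entirely present in multiple copies.
#'
#' @param seed_segment_length Length of the initial random segment.
#' @param n_cycles Number of duplication cycles (>= 1).
#' @param per_cycle_substitution_rate Substitution rate applied to each
#'   appended copy.
#' @param suffix_frac_range Range the suffix fraction is drawn from.
#' @param gc GC content of the seed segment.
#' @param seed_seq Optional explicit seed sequence (overrides length/gc).
#' @return List with `seq` and `segments`, a data.frame recording each
#'   duplicated interval pair (`src_start`, `src_end`, `dst_start`,
#'   `dst_end`, `cycle`, `orientation`).
#' @export
grow_bfb_chromosome <- function(seed_segment_length, n_cycles,
                                per_cycle_substitution_rate = 0,
                                suffix_frac_range = c(0.7, 0.95),
                                gc = 0.42, seed_seq = NULL) {
  if (n_cycles < 1L) stop("n_cycles must be >= 1")
  s <- if (!is.null(seed_seq)) toupper(seed_seq)
       else random_dna(seed_segment_length, gc)
  segs <- data.frame(src_start = integer(0), src_end = integer(0),
                     dst_start = integer(0), dst_end = integer(0),
                     cycle = integer(0), orientation = character(0),
                     stringsAsFactors = FALSE)
  for (cyc in seq_len(n_cycles)) {
    n <- nchar(s)
    frac <- stats::runif(1, suffix_frac_range[1], suffix_frac_range[2])
    slen <- max(1L, min(n, as.integer(round(frac * n))))
    suf <- substr(s, n - slen + 1L, n)
    dup <- mutate_seq(revcomp(suf), per_cycle_substitution_rate)
    segs <- rbind(segs, data.frame(
      src_start = n - slen, src_end = n,
      dst_start = n, dst_end = n + slen,
      cycle = cyc, orientation = "-", stringsAsFactors = FALSE))
    s <- paste0(s, dup)
  }
  list(seq = s, segments = segs)
}

# overwrite part of a chromosome string, returning it; 0-based start
plant_at <- function(chrom_seq, start, piece) {
  substr(chrom_seq, start + 1L, start + nchar(piece)) <- piece
  chrom_seq
}

# make sure no stray aligned telomere copy extends a planted run
break_motif_flanks <- function(s, start, end, motif = "TTAGGG") {
  k <- nchar(motif)
  if (start - k >= 0 && substr(s, start - k + 1L, start) %in%
      c(motif, revcomp(motif))) {
    s <- plant_at(s, start - k, strrep("A", k))
  }
  if (end + k <= nchar(s) && substr(s, end + 1L, end + k) %in%
      c(motif, revcomp(motif))) {
    s <- plant_at(s, end, strrep("A", k))
  }
  s
}

#' Simulate the default desk-scale genome with full ground truth
#'
#' Generates four chromosomes that exercise every analysis stage:
#' \describe{
#'   \item{chr1 (5 Mb)}{a simple centromere (one A-C array), one planted
#'     recombination hotspot, and a 70-copy interstitial telomere array.}
#'   \item{chr2 (6 Mb)}{an asymmetric centromere (A-C array plus B array)
#'     and a 69-copy interstitial telomere array; no hotspots.}
#'   \item{chr3 (8 Mb)}{a symmetric centromere (B array sandwiched between
#'     two A-C arrays in opposite orientation), a 2.5-Mb intra-arm B-array
#'     expansion with 20 orientation blocks, and two hotspots.}
#'   \item{chr4 (~6-9 Mb)}{grown from a 1.2-Mb seed by three
#'     breakage-fusion-bridge cycles; no satellite centromere.}
#' }
#' All chromosomes get terminal telomere arrays of 200-500 exact
#' telomere-motif copies. Genes, flagged GC-outlier genes and genetic-map
#' markers are placed genome-wide. Every planted feature is returned in
#' machine-readable truth tables using 0-based half-open coordinates.
#'
#' @param seed Integer seed; the same seed reproduces the genome exactly.
#' @param mutation_rate Per-copy substitution rate of all satellite
#'   monomer copies (default 0: truth stays base-exact).
#' @param gene_clustering `"uniform"` (null configuration) or
#'   `"near_hotspots"` (outliers planted around hotspot centres).
#' @param hotspot_decay_bp Laplace scale for `"near_hotspots"` placement.
#' @param n_genes,n_outliers Gene counts.
#' @param n_markers_per_chrom Genetic-map markers per chromosome.
#' @param base_rate_cM_per_Mb Background recombination rate.
#' @param cM_noise_sd Gaussian noise on marker cM positions.
#' @param background_gc GC content of the non-repetitive background.
#' @return List with elements `genome` (named [Biostrings::DNAStringSet]),
#'   `monomers`, `truth` (list of data.frames: `centromeres`, `arrays`,
#'   `runs`, `telomeres`, `hotspots`, `markers`, `genes`, `bfb_segments`)
#'   and `config` (the numeric choices used, including the
#'   centromere-caller length bounds scaled to these chromosome sizes).
#' @export
simulate_genome <- function(seed = 1L, mutation_rate = 0,
                            gene_clustering = c("uniform", "near_hotspots"),
                            hotspot_decay_bp = 1e5,
                            n_genes = 400L, n_outliers = 40L,
                            n_markers_per_chrom = 400L,
                            base_rate_cM_per_Mb = 0.5,
                            cM_noise_sd = 0,
                            background_gc = 0.42) {
  gene_clustering <- match.arg(gene_clustering)
  set.seed(seed)
  mono <- default_monomers(mutation_rate = mutation_rate)

  chrom_lengths <- c(chr1 = 5e6, chr2 = 6e6, chr3 = 8e6)  # chr4 comes later

  runs_all <- list()
  arrays_all <- list()
  cens <- list()
  telo_all <- list()

  add_array <- function(chrom, at, built, kind, role) {
    r <- built$runs
    r$start <- r$start + at
    r$end <- r$end + at
    r$chrom <- chrom
    runs_all[[length(runs_all) + 1L]] <<- r
    arrays_all[[length(arrays_all) + 1L]] <<- data.frame(
      chrom = chrom, start = at, end = at + built$length, kind = kind,
      families = paste(unique(r$family), collapse = ","),
      copies = sum(r$copies), n_blocks = length(rle(r$strand)$lengths),
      role = role, stringsAsFactors = FALSE)
    invisible(NULL)
  }

  ac_spec <- function(n_alt) {
    list(kind = "AC", families = c("A", "C"),
         copy_counts = list(A = c(10L, 50L), C = c(5L, 10L)),
         n_alternations = n_alt)
  }
  b_spec <- function(copies, blocks = NULL) {
    list(kind = "homogeneous", families = "B",
         copy_counts = list(B = copies), orientation_blocks = blocks)
  }

  genome <- list()

  ## chr1: simple centromere -------------------------------------------------
  s1 <- random_dna(chrom_lengths[["chr1"]], background_gc)
  cen_at <- 2e6
  a1 <- build_array(ac_spec(600L), mono)
  s1 <- plant_at(s1, cen_at, a1$seq)
  add_array("chr1", cen_at, a1, "AC", "centromere")
  cens$chr1 <- data.frame(chrom = "chr1", start = cen_at,
                          end = cen_at + a1$length, class = "simple",
                          stringsAsFactors = FALSE)
  genome$chr1 <- s1

  ## chr2: asymmetric centromere ---------------------------------------------
  s2 <- random_dna(chrom_lengths[["chr2"]], background_gc)
  at <- 2.4e6
  a2 <- build_array(ac_spec(500L), mono)
  s2 <- plant_at(s2, at, a2$seq)
  add_array("chr2", at, a2, "AC", "centromere")
  at_b <- at + a2$length + 4000
  b2 <- build_array(b_spec(15000L), mono)
  s2 <- plant_at(s2, at_b, b2$seq)
  add_array("chr2", at_b, b2, "B", "centromere")
  cens$chr2 <- data.frame(chrom = "chr2", start = at,
                          end = at_b + b2$length, class = "asymmetric",
                          stringsAsFactors = FALSE)
  genome$chr2 <- s2

  ## chr3: symmetric centromere + intra-arm expansion ------------------------
  s3 <- random_dna(chrom_lengths[["chr3"]], background_gc)
  at <- 3e6
  c1 <- build_array(ac_spec(300L), mono)
  s3 <- plant_at(s3, at, c1$seq)
  add_array("chr3", at, c1, "AC", "centromere")
  at2 <- at + c1$length + 4000
  bm <- build_array(b_spec(8000L), mono)
  s3 <- plant_at(s3, at2, bm$seq)
  add_array("chr3", at2, bm, "B", "centromere")
  at3 <- at2 + bm$length + 4000
  c2_spec <- ac_spec(300L)
  c2_spec$orientation_blocks <- list(list(strand = "-", length = 1))
  c2 <- build_array(c2_spec, mono)
  s3 <- plant_at(s3, at3, c2$seq)
  add_array("chr3", at3, c2, "AC", "centromere")
  cens$chr3 <- data.frame(chrom = "chr3", start = at,
                          end = at3 + c2$length, class = "symmetric",
                          stringsAsFactors = FALSE)
  # 2.5-Mb B expansion with 20 orientation blocks, mean block ~125 kb
  exp_copies <- as.integer(round(2.5e6 / mono$B$length))
  blocks <- lapply(seq_len(20L), function(i) {
    list(strand = if (i %% 2L == 1L) "+" else "-",
         length = stats::runif(1, 0.8, 1.2))
  })
  bx <- build_array(b_spec(exp_copies, blocks), mono)
  exp_at <- 5.2e6
  s3 <- plant_at(s3, exp_at, bx$seq)
  add_array("chr3", exp_at, bx, "B", "expansion")
  genome$chr3 <- s3

  ## chr4: breakage-fusion-bridge chromosome ---------------------------------
  bfb <- grow_bfb_chromosome(seed_segment_length = 1.2e6, n_cycles = 3L,
                             per_cycle_substitution_rate = mutation_rate,
                             gc = background_gc)
  genome$chr4 <- bfb$seq
  chrom_lengths <- c(chrom_lengths, chr4 = nchar(bfb$seq))
  bfb_segments <- cbind(chrom = "chr4", bfb$segments)

  ## telomeres ---------------------------------------------------------------
  motif <- "TTAGGG"
  for (cc in names(genome)) {
    L <- nchar(genome[[cc]])
    nl <- sample(200:500, 1L)
    nr <- sample(200:500, 1L)
    left <- strrep(revcomp(motif), nl)
    right <- strrep(motif, nr)
    genome[[cc]] <- plant_at(genome[[cc]], 0L, left)
    genome[[cc]] <- plant_at(genome[[cc]], L - nchar(right), right)
    genome[[cc]] <- break_motif_flanks(genome[[cc]], 0L, nchar(left))
    genome[[cc]] <- break_motif_flanks(genome[[cc]], L - nchar(right), L)
    telo_all[[length(telo_all) + 1L]] <- data.frame(
      chrom = cc, start = c(0L, L - 6L * nr),
      end = c(6L * nl, L), copies = c(nl, nr),
      strand = c("-", "+"), kind = "terminal", stringsAsFactors = FALSE)
  }
  # interstitial arrays at the copy-number filter edge: 70 kept, 69 rejected
  for (it in list(list(chrom = "chr1", at = 4.2e6, copies = 70L),
                  list(chrom = "chr2", at = 5.0e6, copies = 69L))) {
    piece <- strrep(motif, it$copies)
    genome[[it$chrom]] <- plant_at(genome[[it$chrom]], it$at, piece)
    genome[[it$chrom]] <- break_motif_flanks(genome[[it$chrom]], it$at,
                                             it$at + nchar(piece))
    telo_all[[length(telo_all) + 1L]] <- data.frame(
      chrom = it$chrom, start = it$at, end = it$at + nchar(piece),
      copies = it$copies, strand = "+", kind = "interstitial",
      stringsAsFactors = FALSE)
  }

  ## genetic map -------------------------------------------------------------
  hot_truth <- data.frame(
    chrom = c("chr1", "chr3", "chr3"),
    start = c(3.5e6, 1.0e6, 4.5e6),
    end   = c(3.8e6, 1.3e6, 4.8e6),
    fold  = c(10, 8, 8),
    stringsAsFactors = FALSE)
  markers <- do.call(rbind, lapply(names(genome), function(cc) {
    hs <- hot_truth[hot_truth$chrom == cc, , drop = FALSE]
    simulate_genetic_map(chrom_lengths[[cc]], base_rate_cM_per_Mb,
                         hotspots = if (nrow(hs)) hs else NULL,
                         n_markers = n_markers_per_chrom,
                         cM_noise_sd = cM_noise_sd, chrom = cc)
  }))

  ## genes -------------------------------------------------------------------
  genes <- place_genes(chrom_lengths, n_genes, n_outliers,
                       clustering = gene_clustering,
                       hotspots = hot_truth, decay_bp = hotspot_decay_bp)

  gset <- Biostrings::DNAStringSet(unlist(genome))
  names(gset) <- names(genome)

  list(
    genome = gset,
    monomers = mono,
    truth = list(
      centromeres = do.call(rbind, cens),
      arrays = do.call(rbind, arrays_all),
      runs = do.call(rbind, runs_all),
      telomeres = do.call(rbind, telo_all),
      hotspots = hot_truth,
      markers = markers,
      genes = genes,
      bfb_segments = bfb_segments
    ),
    config = list(
      seed = seed, mutation_rate = mutation_rate,
      gene_clustering = gene_clustering,
      chrom_lengths = chrom_lengths,
      base_rate_cM_per_Mb = base_rate_cM_per_Mb,
      cM_noise_sd = cM_noise_sd,
      background_gc = background_gc,
      # centromere-caller length bounds scaled to these chromosome sizes
      centromere_min_len = 5e5, centromere_max_len = 2e6
    )
  )
}
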