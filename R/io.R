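#' Read chromosome sequences from a FASTA file
#'
#' Sequences are uppercased on ingestion and any character outside
#' A, C, G, T, N is replaced by N (the number of replacements is logged).
#' All internal coordinates in this package are 0-based half-open.
#'
#' @param path Path to a FASTA file with one or more records.
#' @return A named [Biostrings::DNAStringSet]; names are chromosome names.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(ss) == 0L) stop("FASTA file contains no records: ", path)
  nm <- names(ss)
  nm <- sub("\\s.*$", "", nm)  # first token of the header
  if (anyDuplicated(nm)) {
    stop("duplicate record names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  chr <- toupper(as.character(ss))
  n_bad <- sum(vapply(chr, function(s) {
    sum(!seq_chars(s) %in% c("A", "C", "G", "T", "N"))
  }, integer(1)))
  if (n_bad > 0L) {
    chr <- vapply(chr, function(s) gsub("[^ACGTN]", "N", s), character(1))
    rs_log("replaced %d non-ACGTN characters with N while reading %s",
           n_bad, path)
  }
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- nm
  out
}

#' Write chromosome sequences to a FASTA file
#'
#' @param genome A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, filepath = path, format = "fasta")
  invisible(path)
}

#' Read a genetic-map marker table
#'
#' Expects a TSV with header columns `chrom`, `bp` and `cM`. Rows are sorted
#' by (chrom, bp); duplicated (chrom, bp) rows are collapsed to the mean cM
#' and the collapse is logged.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `chrom`, `bp`, `cM`.
#' @export
read_markers <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "bp", "cM")
  if (!all(need %in% names(d))) {
    stop("marker table must have columns chrom, bp, cM")
  }
  d <- d[, need]
  if (!is.numeric(d$bp) || !is.numeric(d$cM)) {
    stop("bp and cM must be numeric")
  }
  if (anyNA(d$bp) || anyNA(d$cM)) stop("non-numeric bp/cM values")
  if (any(d$cM < 0)) stop("negative cM values are not allowed")
  key <- paste(d$chrom, d$bp)
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    d <- stats::aggregate(cM ~ chrom + bp, data = d, FUN = mean)
    rs_log("collapsed %d duplicate (chrom, bp) marker rows to mean cM", n_dup)
  }
  d <- d[order(d$chrom, d$bp), c("chrom", "bp", "cM")]
  rownames(d) <- NULL
  d
}

#' @rdname read_markers
#' @param markers A marker data.frame as returned by [read_markers()].
#' @export
write_markers <- function(markers, path) {
  utils::write.table(markers[, c("chrom", "bp", "cM")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotations
#'
#' Accepts either GFF3 (`gene` features; 1-based closed coordinates,
#' converted to the package-internal 0-based half-open convention) or a
#' tabular file with columns `chrom`, `start`, `end`, `gene_id`,
#' `is_gc_outlier` and optionally `gc3` (already 0-based half-open).
#' In GFF3 the attributes `ID`, `is_gc_outlier` and `gc3` are honoured.
#'
#' @param path Input path; files ending in `.gff`/`.gff3` are parsed as GFF3.
#' @param genome Optional genome ([Biostrings::DNAStringSet]); when supplied,
#'   genes extending beyond their chromosome are an error.
#' @return data.frame with columns `chrom`, `start`, `end`, `gene_id`,
#'   `is_gc_outlier`, `gc3`.
#' @export
read_genes <- function(path, genome = NULL) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    ln <- ln[!grepl("^#", ln) & nzchar(ln)]
    f <- strsplit(ln, "\t", fixed = TRUE)
    f <- f[vapply(f, length, integer(1)) == 9L]
    f <- f[vapply(f, function(x) x[3] == "gene", logical(1))]
    if (length(f) == 0L) stop("no gene features in GFF3: ", path)
    attr_get <- function(a, key) {
      m <- regmatches(a, regexec(paste0("(^|;)", key, "=([^;]*)"), a))[[1]]
      if (length(m) == 0L) NA_character_ else m[3]
    }
    genes <- data.frame(
      chrom = vapply(f, `[`, character(1), 1L),
      start = as.integer(vapply(f, `[`, character(1), 4L)) - 1L,
      end   = as.integer(vapply(f, `[`, character(1), 5L)),
      gene_id = vapply(f, function(x) attr_get(x[9], "ID"), character(1)),
      is_gc_outlier = vapply(f, function(x) {
        v <- attr_get(x[9], "is_gc_outlier")
        !is.na(v) && v %in% c("1", "true", "TRUE")
      }, logical(1)),
      gc3 = vapply(f, function(x) {
        v <- attr_get(x[9], "gc3")
        if (is.na(v)) NA_real_ else as.numeric(v)
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "gene_id", "is_gc_outlier")
    if (!all(need %in% names(d))) {
      stop("tabular gene file must have columns: ",
           paste(need, collapse = ", "))
    }
    genes <- data.frame(
      chrom = as.character(d$chrom),
      start = as.integer(d$start),
      end   = as.integer(d$end),
      gene_id = as.character(d$gene_id),
      is_gc_outlier = as.logical(as.integer(d$is_gc_outlier) != 0L),
      gc3 = if ("gc3" %in% names(d)) as.numeric(d$gc3) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id values")
  if (any(genes$start < 0L) || any(genes$end <= genes$start)) {
    stop("invalid gene intervals (need 0 <= start < end)")
  }
  if (!is.null(genome)) {
    len <- stats::setNames(Biostrings::width(genome), names(genome))
    bad <- is.na(len[genes$chrom]) | genes$end > len[genes$chrom]
    if (any(bad)) {
      stop("gene interval outside chromosome bounds: ",
           paste(utils::head(genes$gene_id[bad], 5), collapse = ", "))
    }
  }
  rownames(genes) <- NULL
  genes
}

#' @rdname read_genes
#' @param genes Gene data.frame (internal 0-based half-open coordinates).
#' @param format `"tsv"` (coordinates written as stored) or `"gff3"`
#'   (converted to 1-based closed).
#' @export
write_genes <- function(genes, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(genes, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    attrs <- sprintf("ID=%s;is_gc_outlier=%d%s", genes$gene_id,
                     as.integer(genes$is_gc_outlier),
                     ifelse(is.na(genes$gc3), "",
                            sprintf(";gc3=%g", genes$gc3)))
    ln <- sprintf("%s\trepeatscape\tgene\t%d\t%d\t.\t.\t.\t%s",
                  genes$chrom, genes$start + 1L, genes$end, attrs)
    writeLines(c("##gff-version 3", ln), path)
  }
  invisible(path)
}

#' Read and write BED intervals
#'
#' Minimal BED3+ support: tab-separated `chrom`, `start`, `end` plus any
#' further columns, carried through untouched so that writing a file read
#' with [read_bed()] reproduces it byte for byte.
#'
#' @param path Path to a BED file.
#' @return data.frame whose first three columns are `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(d) < 3L) stop("BED needs at least 3 columns")
  names(d)[1:3] <- c("chrom", "start", "end")
  if (ncol(d) >= 4L) names(d)[4] <- "name"
  if (ncol(d) >= 5L) names(d)[5] <- "score"
  if (ncol(d) >= 6L) names(d)[6] <- "strand"
  d$start <- as.integer(d$start)
  d$end <- as.integer(d$end)
  if (any(d$start < 0L) || any(d$end <= d$start)) {
    stop("invalid BED intervals")
  }
  d
}

#' @rdname read_bed
#' @param x data.frame with columns `chrom`, `start`, `end` (+ optional more).
#' @export
write_bed <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a window track as bedGraph-style TSV
#'
#' @param track A window track (see [gc_track()]).
#' @param path Output path.
#' @export
write_track <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
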