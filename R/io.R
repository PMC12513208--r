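# Readers/writers for the standard formats the toolkit touches.
# All coordinate conversion between internal (1-based inclusive, the
# R/Bioconductor convention) and file conventions (BED 0-based half-open)
# happens in this file.

#' Read a FASTA file into a sanitized DNAStringSet
#'
#' Sequences are uppercased and every character outside `{A,C,G,T,N}`
#' (IUPAC ambiguity codes, stray letters) is mapped to `N`, so downstream
#' exact matching never has to reason about the extended alphabet. Real
#' assemblies routinely contain IUPAC codes, so these are tolerated rather
#' than rejected.
#'
#' @param path FASTA file, optionally gzip-compressed.
#' @return named [Biostrings::DNAStringSet], records in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgtR"), fa)
#' as.character(readSequences(fa))  # "ACGTN"
#' @export
readSequences <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no sequences in '", path, "'")
  # drop FASTA description after the first whitespace
  names(x) <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(names(x)))) stop("empty sequence id in '", path, "'")
  dup <- names(x)[duplicated(names(x))]
  if (length(dup)) stop("duplicate sequence id(s): ",
                        paste(unique(dup), collapse = ", "))
  if (any(Biostrings::width(x) < 1L)) stop("zero-length sequence in '", path, "'")
  sanitizeSequences(x)
}

#' Sanitize sequences to the {A,C,G,T,N} alphabet
#'
#' @param x `DNAStringSet`, `BStringSet` or named character vector.
#' @return [Biostrings::DNAStringSet] with all non-ACGTN characters as `N`.
#' @export
sanitizeSequences <- function(x) {
  chr <- toupper(as.character(x))
  chr <- gsub("[^ACGTN]", "N", chr, perl = TRUE)
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(x)
  out
}

#' Write sequences to FASTA
#'
#' @param x named `DNAStringSet` (or coercible).
#' @param path output file; `.gz` suffix triggers gzip compression.
#' @param width line width, default 80.
#' @return `path`, invisibly.
#' @export
writeSequences <- function(x, path, width = 80L) {
  if (!methods::is(x, "XStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

.BLAST6_COLS <- c("query_id", "subject_id", "pident", "aln_len", "mismatch",
                  "gapopen", "q_start", "q_end", "s_start", "s_end",
                  "evalue", "bitscore")

#' Read marker-to-assembly alignments (BLAST outfmt-6 or PAF)
#'
#' Both dialects are normalized to a common alignment table with the twelve
#' BLAST tabular columns. Minus-strand alignments are encoded by
#' `s_start > s_end` (the blastn convention); PAF rows, which carry an
#' explicit strand column and 0-based half-open coordinates, are converted
#' accordingly, with percent identity computed as
#' `matches / block_length * 100`.
#'
#' @param path tab-separated alignment file.
#' @param dialect `"blast6"` (12 columns: qseqid sseqid pident length
#'   mismatch gapopen qstart qend sstart send evalue bitscore) or `"paf"`
#'   (first 12 standard PAF columns; extra tag columns are ignored).
#' @return data.frame with columns `query_id, subject_id, pident, aln_len,
#'   mismatch, gapopen, q_start, q_end, s_start, s_end, evalue, bitscore`;
#'   all coordinates 1-based inclusive.
#' @export
readAlignmentTable <- function(path, dialect = c("blast6", "paf")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- as.data.frame(matrix(nrow = 0, ncol = 12))
    names(out) <- .BLAST6_COLS
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- 12L
  bad <- which(nf < need | (dialect == "blast6" & nf != need))
  if (length(bad))
    stop(sprintf("line %d of '%s': expected %s12 tab-separated columns, got %d",
                 bad[1L], path, if (dialect == "paf") ">= " else "", nf[bad[1L]]))
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  if (dialect == "blast6") {
    out <- data.frame(
      query_id = m[, 1], subject_id = m[, 2],
      pident = as.numeric(m[, 3]), aln_len = as.integer(m[, 4]),
      mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
      q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
      s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
      evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
      stringsAsFactors = FALSE)
  } else {
    # PAF: qname qlen qstart qend strand tname tlen tstart tend
    #      matches blocklen mapq  (coordinates 0-based half-open)
    strand <- m[, 5]
    if (!all(strand %in% c("+", "-")))
      stop("PAF strand column must be '+' or '-'")
    matches <- as.numeric(m[, 10]); block <- as.numeric(m[, 11])
    t_start1 <- as.integer(m[, 8]) + 1L
    t_end1 <- as.integer(m[, 9])
    out <- data.frame(
      query_id = m[, 1], subject_id = m[, 6],
      pident = matches / block * 100,
      aln_len = as.integer(block),
      mismatch = as.integer(block - matches), gapopen = 0L,
      q_start = as.integer(m[, 3]) + 1L, q_end = as.integer(m[, 4]),
      s_start = ifelse(strand == "+", t_start1, t_end1),
      s_end = ifelse(strand == "+", t_end1, t_start1),
      evalue = NA_real_, bitscore = matches,
      stringsAsFactors = FALSE)
  }
  .validateAlignmentRows(out, path)
  out
}

.validateAlignmentRows <- function(df, what = "alignment table") {
  if (any(df$pident < 0 | df$pident > 100))
    stop("pident outside [0, 100] in ", what)
  if (any(df$aln_len < 1L)) stop("aln_len < 1 in ", what)
  if (any(df[, c("q_start", "q_end", "s_start", "s_end")] < 1L))
    stop("coordinates must be >= 1 in ", what)
  invisible(df)
}

#' Alignment strand from the subject coordinate convention
#'
#' @param rows alignment data.frame as from [readAlignmentTable()].
#' @return character vector of `"+"`/`"-"` (`s_start > s_end` is minus).
#' @export
alignmentStrand <- function(rows) {
  ifelse(rows$s_start <= rows$s_end, "+", "-")
}

#' Write rearrangement calls as BED-like TSV
#'
#' Output columns are `chrom`, `start` (0-based half-open, BED convention),
#' `end`, `type`, `n_markers`, `subject_scaffold`, `assembly`, and `region`,
#' a human-readable 1-based inclusive string (`"chr8:8200001-12100001"`).
#'
#' @param calls `GRanges` of calls (1-based inclusive) with metadata columns
#'   `type`, `n_markers`, `subject_id`, `assembly_label`, as produced by
#'   [callInversions()] / [callTranslocations()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @seealso [readCalls()]
#' @export
writeCalls <- function(calls, path) {
  df <- callsToTable(calls)
  .writeTsv(df, path)
}

#' Rearrangement calls as a BED-like data.frame
#'
#' @inheritParams writeCalls
#' @return data.frame in the [writeCalls()] column layout.
#' @export
callsToTable <- function(calls) {
  stopifnot(methods::is(calls, "GRanges"))
  mc <- S4Vectors::mcols(calls)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(calls)),
    start = GenomicRanges::start(calls) - 1L,   # BED 0-based half-open
    end = GenomicRanges::end(calls),
    type = as.character(mc$type),
    n_markers = as.integer(mc$n_markers),
    subject_scaffold = as.character(mc$subject_id),
    assembly = as.character(mc$assembly_label),
    region = .regionString(as.character(GenomicRanges::seqnames(calls)),
                           GenomicRanges::start(calls),
                           GenomicRanges::end(calls)),
    stringsAsFactors = FALSE)
}

#' Read rearrangement calls written by [writeCalls()]
#'
#' @param path BED-like TSV produced by [writeCalls()].
#' @return `GRanges` with 1-based inclusive intervals and metadata columns
#'   `type`, `n_markers`, `subject_id`, `assembly_label`.
#' @export
readCalls <- function(path) {
  df <- .readTsv(path, colClasses = c(chrom = "character",
                                      subject_scaffold = "character",
                                      assembly = "character"))
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    type = df$type, n_markers = as.integer(df$n_markers),
    subject_id = df$subject_scaffold, assembly_label = df$assembly)
}
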