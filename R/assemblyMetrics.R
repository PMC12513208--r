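# Contiguity statistics and seeded FASTQ subsampling for coverage titration.

#' Scaffold contiguity statistics (N50, L50, size, ambiguous bases)
#'
#' Sorts scaffold lengths in decreasing order; L50 is the smallest k whose
#' cumulative length reaches at least half the assembly total (>= half, the
#' convention under which a complete 23-chromosome human assembly gives an
#' L50 of 8-9), and N50 is the k-th length.
#'
#' @param seqs named `DNAStringSet`, FASTA path, or a numeric vector of
#'   scaffold lengths (N count then reported as 0).
#' @return an [AssemblyStats-class] object.
#' @examples
#' scaffoldStats(10:1)  # N50 7, L50 4
#' @export
scaffoldStats <- function(seqs) {
  if (is.character(seqs) && length(seqs) == 1L) seqs <- readSequences(seqs)
  if (is.numeric(seqs)) {
    lens <- as.numeric(seqs)
    nN <- 0
  } else {
    stopifnot(methods::is(seqs, "XStringSet"))
    lens <- as.numeric(Biostrings::width(seqs))
    nN <- sum(Biostrings::letterFrequency(seqs, "N")[, 1L])
  }
  if (length(lens) == 0L) stop("no scaffolds")
  if (any(lens < 1)) stop("zero-length scaffold")
  lens <- sort(lens, decreasing = TRUE)
  csum <- cumsum(lens)
  total <- csum[length(csum)]
  l50 <- which(csum >= total / 2)[1L]
  methods::new("AssemblyStats",
               nScaffolds = length(lens), totalBp = total,
               n50 = lens[l50], l50 = as.integer(l50),
               nAmbiguous = nN, longest = lens[1L])
}

#' Seeded per-read Bernoulli subsampling of a FASTQ to target coverage
#'
#' Mirrors seqtk-style fraction sampling: each read is kept independently
#' with probability `p = coverage * genomeSize / totalBases`, preserving
#' input order; the same seed always yields byte-identical output. If the
#' input holds fewer bases than the target, all reads are returned with a
#' warning.
#'
#' @param input FASTQ path (gzip ok).
#' @param output output FASTQ path; `NULL` returns the kept reads invisibly
#'   without writing.
#' @param coverage target fold coverage (> 0).
#' @param genomeSize genome size in bp (> 0).
#' @param seed integer RNG seed.
#' @return invisibly, a list with `n_in`, `n_out`, `bases_out`, `p`.
#' @export
subsampleReads <- function(input, output, coverage, genomeSize, seed) {
  if (coverage <= 0) stop("coverage must be positive")
  if (genomeSize <= 0) stop("genomeSize must be positive")
  reads <- Biostrings::readDNAStringSet(input, format = "fastq",
                                        with.qualities = TRUE)
  B <- sum(as.numeric(Biostrings::width(reads)))
  target <- coverage * genomeSize
  p <- target / B
  if (p >= 1) {
    if (p > 1)
      warning(sprintf("input holds %.0f bases < target %.0f; returning all reads",
                      B, target))
    p <- 1
    keep <- rep(TRUE, length(reads))
  } else {
    keep <- .withSeed(seed, stats::runif(length(reads)) < p)
  }
  kept <- reads[keep]
  if (!is.null(output)) {
    Biostrings::writeXStringSet(
      kept, output, format = "fastq",
      qualities = S4Vectors::mcols(reads)$qualities[keep],
      compress = grepl("\\.gz$", output))
  }
  invisible(list(n_in = length(reads), n_out = length(kept),
                 bases_out = sum(as.numeric(Biostrings::width(kept))),
                 p = p, reads = kept))
}

#' Aggregate contiguity statistics over coverage-titration replicates
#'
#' For each coverage level, computes the mean and standard deviation of
#' N50, L50 and total assembly size across replicate assemblies — the table
#' behind a coverage-versus-contiguity titration curve.
#'
#' @param replicateSets named list: `coverage label -> list/vector` of
#'   FASTA paths (or `DNAStringSet`s, or numeric length vectors).
#' @return data.frame with columns `coverage`, `n_replicates`, and
#'   mean/sd of `N50`, `L50`, `total_bp`.
#' @export
titrationTable <- function(replicateSets) {
  if (!length(replicateSets) || is.null(names(replicateSets)))
    stop("replicateSets must be a non-empty named list")
  rows <- lapply(names(replicateSets), function(cov) {
    reps <- replicateSets[[cov]]
    stats <- lapply(reps, function(r) as.data.frame(scaffoldStats(r)))
    st <- do.call(rbind, stats)
    data.frame(coverage = cov, n_replicates = nrow(st),
               N50_mean = mean(st$N50),
               N50_sd = if (nrow(st) > 1) stats::sd(st$N50) else 0,
               L50_mean = mean(st$L50),
               L50_sd = if (nrow(st) > 1) stats::sd(st$L50) else 0,
               total_bp_mean = mean(st$total_bp),
               total_bp_sd = if (nrow(st) > 1) stats::sd(st$total_bp) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
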