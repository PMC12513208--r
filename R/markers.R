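# Virtual-marker generation: fixed-length windows on a 1-anchored grid
# along each reference chromosome.

#' Generate a virtual marker set from a reference genome
#'
#' Extracts `markerLen`-bp windows starting at 1-based positions
#' `1, spacing + 1, 2 * spacing + 1, ...` on every reference chromosome,
#' keeping a window only if it fits entirely on the chromosome and its
#' fraction of ambiguous bases (N) does not exceed `maxAmbiguousFrac`.
#' The defaults (2-kb markers every 1 Mb) reproduce the low-resolution
#' whole-genome marker construction; `spacing = 1e5` gives the
#' high-resolution set that resolves rearrangements down to a few hundred kb.
#'
#' The grid is anchored at position 1 (not `spacing`), so marker starts and
#' every grid-snapped breakpoint derived from them have the form
#' `k * spacing + 1`.
#'
#' @param reference named `DNAStringSet` (see [readSequences()]) or a file
#'   path to a FASTA.
#' @param spacing grid spacing in bp (default 1e6).
#' @param markerLen marker length in bp (default 2000); must be `< spacing`.
#' @param maxAmbiguousFrac maximum tolerated N fraction per window
#'   (default 0.2); windows above it are skipped (they sit over assembly
#'   gaps and would be unalignable).
#' @return a [MarkerSet-class] object. Chromosomes shorter than `markerLen`
#'   are skipped with a warning, not an error.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 7.5e5), collapse = "")))
#' ms <- generateMarkers(ref, spacing = 1e6, markerLen = 2000)
#' markerTable(ms)  # markers at 1, 1000001, 2000001
#' @export
generateMarkers <- function(reference, spacing = 1e6, markerLen = 2000,
                            maxAmbiguousFrac = 0.2) {
  if (is.character(reference) && length(reference) == 1L)
    reference <- readSequences(reference)
  stopifnot(methods::is(reference, "DNAStringSet"))
  if (is.null(names(reference)) || any(!nzchar(names(reference))))
    stop("reference sequences must be named")
  if (markerLen >= spacing) stop("markerLen must be smaller than spacing")

  all_chrom <- character(0); all_start <- integer(0)
  seq_list <- vector("list", length(reference))
  for (i in seq_along(reference)) {
    chrom <- names(reference)[i]
    L <- Biostrings::width(reference)[i]
    if (L < markerLen) {
      warning("chromosome '", chrom, "' (", L,
              " bp) is shorter than markerLen; skipped")
      next
    }
    starts <- seq.int(1L, L - markerLen + 1L, by = spacing)
    win <- Biostrings::extractAt(
      reference[[i]],
      IRanges::IRanges(start = starts, width = markerLen))
    nfrac <- Biostrings::letterFrequency(win, "N", as.prob = TRUE)[, 1L]
    keep <- nfrac <= maxAmbiguousFrac
    if (!any(keep)) next
    win <- win[keep]
    names(win) <- paste0(chrom, "_", starts[keep])
    seq_list[[i]] <- win
    all_chrom <- c(all_chrom, rep(chrom, sum(keep)))
    all_start <- c(all_start, as.integer(starts[keep]))
  }
  seq_list <- seq_list[!vapply(seq_list, is.null, logical(1))]
  seqs <- if (length(seq_list)) do.call(c, seq_list) else
    Biostrings::DNAStringSet()
  methods::new("MarkerSet", seqs = seqs, chrom = all_chrom,
               start = all_start, spacing = spacing, markerLen = markerLen,
               maxAmbiguousFrac = maxAmbiguousFrac)
}

#' Write a MarkerSet to FASTA
#'
#' Marker ids `"{chrom}_{start1}"` become the FASTA headers, so the grid
#' coordinates survive a round trip through external aligners.
#'
#' @param markers a `MarkerSet`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeMarkers <- function(markers, path) {
  stopifnot(methods::is(markers, "MarkerSet"))
  writeSequences(markerSeqs(markers), path)
}

#' Read a marker FASTA back into a MarkerSet
#'
#' Coordinates are recovered from the `"{chrom}_{start1}"` ids; the grid
#' geometry cannot be read from FASTA and must be restated.
#'
#' @param path marker FASTA written by [writeMarkers()].
#' @param spacing,maxAmbiguousFrac grid geometry of the set.
#' @return a [MarkerSet-class].
#' @export
readMarkers <- function(path, spacing = 1e6, maxAmbiguousFrac = 0.2) {
  seqs <- readSequences(path)
  info <- .parseMarkerId(names(seqs))
  ord <- order(info$chrom, info$start)
  seqs <- seqs[ord]; info <- info[ord, ]
  methods::new("MarkerSet", seqs = seqs, chrom = info$chrom,
               start = as.integer(info$start), spacing = spacing,
               markerLen = unique(Biostrings::width(seqs))[1],
               maxAmbiguousFrac = maxAmbiguousFrac)
}
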