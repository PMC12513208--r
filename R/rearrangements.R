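# Inversion/translocation calling from signed blocks, grid-snapped
# breakpoint reporting, detection-limit arithmetic, breakpoint-spanning
# read counts, and multi-assembly genotype matrices.

.newCalls <- function(chrom, start, end, type, n_markers, subject_id,
                      assembly_label) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    type = type, n_markers = as.integer(n_markers),
    subject_id = subject_id, assembly_label = assembly_label)
}

.emptyCalls <- function() {
  .newCalls(character(0), integer(0), integer(0), character(0), integer(0),
            character(0), character(0))
}

#' Call large inversions from signed collinear blocks
#'
#' Every reverse (sign -1) block supported by at least `minMarkers` markers
#' becomes an inversion call. The reported reference interval is snapped to
#' the marker grid: `[first inverted marker start, last inverted marker
#' start + spacing]`, 1-based inclusive, so both endpoints have the
#' `k * spacing + 1` form and each true breakpoint lies within one grid
#' step of the reported one. With the default `minMarkers = 2`, events
#' shorter than roughly two grid steps cannot be guaranteed to contain
#' enough markers and are missed by construction — see
#' [guaranteedDetectableLength()].
#'
#' @param blocks data.frame from [segmentBlocks()].
#' @param spacing marker grid spacing in bp.
#' @param minMarkers minimum supporting markers per call (default 2;
#'   raise to 3 for noisy data).
#' @param assemblyLabel label recorded on each call (default `"assembly"`).
#' @return `GRanges` of calls with metadata `type`, `n_markers`,
#'   `subject_id`, `assembly_label`.
#' @export
callInversions <- function(blocks, spacing, minMarkers = 2,
                           assemblyLabel = "assembly") {
  inv <- blocks[blocks$sign == -1L & blocks$n_markers >= minMarkers, ,
                drop = FALSE]
  if (nrow(inv) == 0L) return(.emptyCalls())
  .newCalls(chrom = inv$chrom,
            start = inv$ref_start,
            end = inv$ref_end + spacing,
            type = "inversion", n_markers = inv$n_markers,
            subject_id = inv$subject_id, assembly_label = assemblyLabel)
}

#' Call translocations from markers landing on foreign scaffolds
#'
#' A maximal run of at least `minMarkers` consecutive (in reference grid
#' order) unambiguous markers whose best hits lie on one scaffold assigned
#' to a *different* chromosome becomes a translocation call, with the same
#' grid-snapping rule as inversions.
#'
#' @param placements data.frame from [bestHits()].
#' @param assignments data.frame from [assignScaffolds()].
#' @param spacing marker grid spacing in bp.
#' @param minMarkers minimum run length (default 2).
#' @param assemblyLabel label recorded on each call.
#' @return `GRanges` of calls (see [callInversions()]).
#' @export
callTranslocations <- function(placements, assignments, spacing,
                               minMarkers = 2, assemblyLabel = "assembly") {
  p <- placements[!placements$ambiguous, , drop = FALSE]
  if (nrow(p) == 0L) return(.emptyCalls())
  assigned <- stats::setNames(assignments$chrom, assignments$subject_id)
  p$assigned_chrom <- assigned[p$subject_id]
  p <- p[order(p$ref_chrom, p$ref_start), , drop = FALSE]
  calls <- list()
  for (chrom in unique(p$ref_chrom)) {
    q <- p[p$ref_chrom == chrom, , drop = FALSE]
    foreign <- !is.na(q$assigned_chrom) & q$assigned_chrom != chrom
    if (!any(foreign)) next
    # runs of foreign markers on the same scaffold
    run_break <- c(TRUE, foreign[-1L] != foreign[-nrow(q)] |
                     q$subject_id[-1L] != q$subject_id[-nrow(q)])
    rid <- cumsum(run_break)
    for (b in split(seq_len(nrow(q)), rid)) {
      if (!foreign[b[1L]] || length(b) < minMarkers) next
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = chrom,
        start = q$ref_start[b[1L]],
        end = q$ref_start[b[length(b)]] + spacing,
        n_markers = length(b), subject_id = q$subject_id[b[1L]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(.emptyCalls())
  df <- do.call(rbind, calls)
  .newCalls(df$chrom, df$start, df$end, "translocation", df$n_markers,
            df$subject_id, assemblyLabel)
}

#' Minimum rearrangement length guaranteed to contain k full markers
#'
#' Computes, by brute force over every integer placement offset, the
#' smallest interval length L such that an interval of length L starting at
#' *any* offset fully contains at least `minMarkers` markers of the grid
#' `{0, s, 2s, ...}`, each of length `m`. This is the guaranteed detection
#' limit of marker-based rearrangement calling: with 2-kb markers every
#' 1 Mb and `minMarkers = 2` it is 2,001,999 bp (events under ~2 Mb can
#' slip between markers), and at 100-kb spacing it is 201,999 bp (~200 kb).
#'
#' The closed form is `minMarkers * s + m - 1`; the brute force is the
#' definition and the closed form is checked against it in the test suite.
#'
#' @param spacing grid spacing s in bp.
#' @param markerLen marker length m in bp (`markerLen < spacing`).
#' @param minMarkers required number of fully contained markers.
#' @param bruteForce if `TRUE` (default) sweep all offsets `0..s-1`;
#'   otherwise return the closed form.
#' @return length in bp.
#' @export
guaranteedDetectableLength <- function(spacing, markerLen, minMarkers = 2,
                                       bruteForce = TRUE) {
  s <- as.numeric(spacing); m <- as.numeric(markerLen)
  k <- as.integer(minMarkers)
  if (!(s > m) || m < 1) stop("need spacing > markerLen >= 1")
  if (k < 1) stop("minMarkers must be >= 1")
  if (!bruteForce) return(k * s + m - 1)
  # For offset a, the first whole marker in [a, a+L) starts at s*ceil(a/s);
  # the k-th after it ends at s*ceil(a/s) + (k-1)*s + m. The minimal L that
  # works at offset a is that end minus a; the guarantee is the max over a.
  a <- seq.int(0, s - 1)
  first <- s * ceiling(a / s)
  L_a <- first + (k - 1) * s + m - a
  max(L_a)
}

#' Count alignments spanning a breakpoint with flanking anchors
#'
#' An alignment supports (refutes an inversion at) a breakpoint when it
#' covers the breakpoint plus `flank` bp on both sides: few or no spanning
#' raw reads at a predicted breakpoint is the read-level validation signal
#' for a true rearrangement.
#'
#' @param alignments data.frame with columns `start`, `end` (reference
#'   coordinates of read alignments, 1-based inclusive), e.g. derived from
#'   a PAF via [readAlignmentTable()] (`s_start`/`s_end`) or a BED.
#' @param breakpoint reference position.
#' @param flank required anchor on each side in bp (default 10,000);
#'   must be positive. Boundary is inclusive: an alignment ending exactly
#'   at `breakpoint + flank` counts.
#' @return integer count of spanning alignments.
#' @export
spanSupport <- function(alignments, breakpoint, flank = 10000) {
  if (flank <= 0) stop("flank must be positive")
  sum(alignments$start <= breakpoint - flank &
        alignments$end >= breakpoint + flank)
}

#' Merge calls across assemblies into a genotype matrix
#'
#' Calls of the same type on the same chromosome are single-linkage merged
#' when their reciprocal overlap reaches `reciprocalOverlap`; each merged
#' locus becomes a row and each assembly a column, with `TRUE` where the
#' assembly contributed a call — a presence/absence table of shared large
#' rearrangements across individuals.
#'
#' @param calls `GRanges` of calls pooled over assemblies (concatenate the
#'   per-assembly call sets; `assembly_label` distinguishes them).
#' @param assemblies character vector of assembly labels defining the
#'   column order (default: labels present in `calls`).
#' @param reciprocalOverlap merge threshold in [0, 1] (default 0.8).
#' @return list with `loci` (`GRanges` of merged intervals, metadata `type`
#'   and `region`) and `matrix` (logical, loci x assemblies).
#' @export
genotypeMatrix <- function(calls, assemblies = NULL,
                           reciprocalOverlap = 0.8) {
  stopifnot(methods::is(calls, "GRanges"))
  if (is.null(assemblies))
    assemblies <- sort(unique(S4Vectors::mcols(calls)$assembly_label))
  n <- length(calls)
  if (n == 0L) {
    return(list(loci = .emptyCalls(),
                matrix = matrix(logical(0), nrow = 0,
                                ncol = length(assemblies),
                                dimnames = list(NULL, assemblies))))
  }
  hits <- GenomicRanges::findOverlaps(calls, calls)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  keep <- qh < sh &
    S4Vectors::mcols(calls)$type[qh] == S4Vectors::mcols(calls)$type[sh]
  qh <- qh[keep]; sh <- sh[keep]
  if (length(qh)) {
    ov <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(calls)[qh], GenomicRanges::ranges(calls)[sh]))
    rec <- ov / GenomicRanges::width(calls)[qh] >= reciprocalOverlap &
      ov / GenomicRanges::width(calls)[sh] >= reciprocalOverlap
    qh <- qh[rec]; sh <- sh[rec]
  }
  comp <- .unionFind(n, cbind(qh, sh))
  loci_list <- split(seq_len(n), comp)
  # loci on disjoint chromosomes are expected; the combine warning is noise
  loci <- suppressWarnings(do.call(c, unname(lapply(loci_list, function(i) {
    GenomicRanges::GRanges(
      seqnames = as.character(GenomicRanges::seqnames(calls))[i[1L]],
      ranges = IRanges::IRanges(
        start = min(GenomicRanges::start(calls)[i]),
        end = max(GenomicRanges::end(calls)[i])),
      type = S4Vectors::mcols(calls)$type[i[1L]])
  }))))
  S4Vectors::mcols(loci)$region <- .regionString(
    as.character(GenomicRanges::seqnames(loci)),
    GenomicRanges::start(loci), GenomicRanges::end(loci))
  mat <- matrix(FALSE, nrow = length(loci_list), ncol = length(assemblies),
                dimnames = list(S4Vectors::mcols(loci)$region, assemblies))
  lab <- as.character(S4Vectors::mcols(calls)$assembly_label)
  for (r in seq_along(loci_list))
    mat[r, unique(lab[loci_list[[r]]])] <- TRUE
  list(loci = loci, matrix = mat)
}
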