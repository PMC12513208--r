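# Scaffold-to-chromosome assignment, orientation normalization, signed
# collinear-block segmentation and linearity/completeness metrics.

#' Assign scaffolds to reference chromosomes by marker majority vote
#'
#' Each scaffold is assigned to the chromosome contributing the majority of
#' its placed markers (ties resolved deterministically to the
#' lexicographically smaller chromosome name, with a message). A scaffold's
#' orientation is the majority strand of its supporting markers — Hi-C
#' scaffolds have arbitrary strand, and downstream block signs are defined
#' relative to this dominant orientation. The longest scaffold assigned to
#' each chromosome is marked primary.
#'
#' @param placements data.frame from [bestHits()].
#' @param assemblyLengths named numeric vector of scaffold lengths (bp).
#' @return data.frame with columns `subject_id`, `chrom`, `n_support`,
#'   `orientation` (`"+"`/`"-"`), `is_primary`, `subject_length`.
#' @export
assignScaffolds <- function(placements, assemblyLengths) {
  if (nrow(placements) == 0L) stop("no placements to assign")
  bys <- split(placements, placements$subject_id)
  res <- lapply(bys, function(p) {
    counts <- sort(table(p$ref_chrom), decreasing = TRUE)
    top <- counts[counts == counts[1L]]
    chrom <- sort(names(top))[1L]
    if (length(top) > 1L)
      message("scaffold '", p$subject_id[1L], "': chromosome vote tie (",
              paste(names(top), collapse = ", "), "); assigned '", chrom, "'")
    supp <- p[p$ref_chrom == chrom, , drop = FALSE]
    n_minus <- sum(supp$strand == "-")
    data.frame(subject_id = p$subject_id[1L], chrom = chrom,
               n_support = nrow(supp),
               orientation = if (n_minus * 2L > nrow(supp)) "-" else "+",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$subject_length <- unname(assemblyLengths[out$subject_id])
  if (anyNA(out$subject_length))
    stop("assemblyLengths missing for scaffold(s): ",
         paste(out$subject_id[is.na(out$subject_length)], collapse = ", "))
  out$is_primary <- FALSE
  for (ch in unique(out$chrom)) {
    i <- which(out$chrom == ch)
    out$is_primary[i[which.max(out$subject_length[i])]] <- TRUE
  }
  out[order(out$chrom, -out$subject_length), , drop = FALSE]
}

# Orientation-normalize placements: flip strand and mirror subject
# coordinates on scaffolds whose dominant orientation is "-", so that a
# wholly reverse-complemented scaffold looks identical to a forward one.
# Adds columns `norm_strand` and `norm_pos` (1-based leftmost coordinate of
# the marker in the normalized scaffold frame).
.normalizePlacements <- function(placements, assignments) {
  orient <- stats::setNames(assignments$orientation, assignments$subject_id)
  slen <- stats::setNames(assignments$subject_length, assignments$subject_id)
  o <- orient[placements$subject_id]
  if (anyNA(o)) stop("placements on scaffolds absent from assignments")
  flip <- o == "-"
  placements$norm_strand <- ifelse(
    flip, ifelse(placements$strand == "+", "-", "+"), placements$strand)
  L <- slen[placements$subject_id]
  placements$norm_pos <- ifelse(
    flip, L - (placements$subject_start + placements$aln_len - 1L) + 1L,
    placements$subject_start)
  placements
}

#' Segment placed markers into signed collinear blocks
#'
#' Walks the unambiguous markers of each reference chromosome in grid order
#' and chains them into maximal blocks: a marker extends the current block
#' while it stays on the same scaffold, keeps the same orientation-normalized
#' strand, and its positional jump on the scaffold is consistent with the
#' jump on the reference (`|delta_subject - sign * delta_ref| <=
#' gapTol * spacing`). Forward blocks (sign +1) are dot-plot diagonals;
#' reverse blocks (sign -1) are anti-diagonals, the signature of inversions.
#'
#' @param placements data.frame from [bestHits()] (ambiguous markers are
#'   dropped internally).
#' @param assignments data.frame from [assignScaffolds()] (supplies each
#'   scaffold's dominant orientation and length).
#' @param spacing marker grid spacing in bp.
#' @param gapTol tolerated positional jump in grid steps before a block is
#'   broken (default 3; tolerates isolated masked or failed markers).
#' @return data.frame with columns `chrom`, `subject_id`, `sign` (+1/-1),
#'   `ref_start`, `ref_end` (first/last member marker starts, 1-based),
#'   `subject_start`, `subject_end` (normalized scaffold frame),
#'   `n_markers`.
#' @export
segmentBlocks <- function(placements, assignments, spacing, gapTol = 3) {
  p <- placements[!placements$ambiguous, , drop = FALSE]
  if (nrow(p) == 0L) return(.emptyBlocks())
  p <- .normalizePlacements(p, assignments)
  p <- p[order(p$ref_chrom, p$ref_start), , drop = FALSE]
  blocks <- list()
  for (chrom in unique(p$ref_chrom)) {
    q <- p[p$ref_chrom == chrom, , drop = FALSE]
    sgn <- ifelse(q$norm_strand == "+", 1L, -1L)
    newblock <- rep(TRUE, nrow(q))
    if (nrow(q) > 1L) {
      i <- 2:nrow(q)
      same <- q$subject_id[i] == q$subject_id[i - 1L] &
        sgn[i] == sgn[i - 1L]
      dref <- q$ref_start[i] - q$ref_start[i - 1L]
      dsub <- q$norm_pos[i] - q$norm_pos[i - 1L]
      ok <- same & abs(dsub - sgn[i] * dref) <= gapTol * spacing
      newblock[i] <- !ok
    }
    bid <- cumsum(newblock)
    for (b in split(seq_len(nrow(q)), bid)) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom = chrom, subject_id = q$subject_id[b[1L]],
        sign = sgn[b[1L]],
        ref_start = q$ref_start[b[1L]], ref_end = q$ref_start[b[length(b)]],
        subject_start = q$norm_pos[b[1L]],
        subject_end = q$norm_pos[b[length(b)]],
        n_markers = length(b), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

.emptyBlocks <- function() {
  data.frame(chrom = character(0), subject_id = character(0),
             sign = integer(0), ref_start = integer(0), ref_end = integer(0),
             subject_start = integer(0), subject_end = integer(0),
             n_markers = integer(0), stringsAsFactors = FALSE)
}

#' Per-chromosome linearity and completeness metrics
#'
#' For each reference chromosome reports: `marker_recovery`, the fraction of
#' expected markers placed anywhere; `primary_recovery`, the fraction placed
#' on the chromosome's primary (longest assigned) scaffold — the quantity
#' behind "the longest scaffolds cover over 95% of the respective
#' chromosomes"; and `collinearity`, the length of the longest strictly
#' increasing subsequence of orientation-normalized scaffold positions on
#' the primary scaffold divided by placed markers, a dot-plot "fraction on
#' the diagonal" statistic (1.0 = perfectly linear).
#'
#' @param placements data.frame from [bestHits()].
#' @param assignments data.frame from [assignScaffolds()].
#' @param markers the [MarkerSet-class] used for mapping (supplies expected
#'   marker counts per chromosome).
#' @return data.frame with columns `chrom`, `n_expected`, `n_placed`,
#'   `marker_recovery`, `primary_recovery`, `collinearity`.
#' @export
linearityMetrics <- function(placements, assignments, markers) {
  stopifnot(methods::is(markers, "MarkerSet"))
  mt <- markerTable(markers)
  expected <- table(mt$chrom)
  p <- placements[!placements$ambiguous, , drop = FALSE]
  p <- .normalizePlacements(p, assignments)
  primary <- stats::setNames(assignments$is_primary, assignments$subject_id)
  chrom_primary <- assignments$subject_id[assignments$is_primary]
  names(chrom_primary) <- assignments$chrom[assignments$is_primary]
  res <- lapply(names(expected), function(ch) {
    q <- p[p$ref_chrom == ch, , drop = FALSE]
    n_exp <- as.integer(expected[[ch]])
    n_placed <- nrow(q)
    prim <- chrom_primary[ch]
    qp <- q[!is.na(prim) & q$subject_id == prim, , drop = FALSE]
    lis <- if (nrow(qp)) .lisLength(qp$norm_pos[order(qp$ref_start)]) else 0L
    data.frame(chrom = ch, n_expected = n_exp, n_placed = n_placed,
               marker_recovery = n_placed / n_exp,
               primary_recovery = nrow(qp) / n_exp,
               collinearity = if (n_placed) lis / n_placed else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
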