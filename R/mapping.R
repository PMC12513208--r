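# Marker placement: built-in exact-seed / ungapped-extension matcher for
# desk-scale data, plus the identity filtering and best-hit selection rules
# applied to either built-in or imported (blastn/PAF) alignments.

#' Place markers on an assembly with the built-in matcher
#'
#' A seed-and-extend matcher sufficient for assemblies that differ from the
#' reference by substitutions and rearrangements (the regime the simulator
#' produces): exact `seedLen`-mers sampled along each marker are matched
#' against both strands of every scaffold; each distinct implied marker
#' offset becomes a candidate locus, scored by ungapped comparison over the
#' full marker length. Percent identity is `matches / markerLen * 100`.
#' Candidate loci that would run off a scaffold end are discarded (the
#' matcher is full-length only). Indel-bearing loci are out of reach by
#' design; import real aligner output via [readAlignmentTable()] for those.
#'
#' @param markers a [MarkerSet-class].
#' @param assembly named `DNAStringSet` of scaffolds (or FASTA path).
#' @param seedLen exact seed length in bp (default 21).
#' @param seedStride distance between sampled seed starts within a marker
#'   (default 250 bp); denser seeding tolerates more substitutions.
#' @param minReportPident report only candidates with percent identity at
#'   least this (default 80).
#' @return alignment data.frame in [readAlignmentTable()] layout
#'   (minus strand encoded as `s_start > s_end`; `bitscore` is the match
#'   count, a convenience score — built-in selection uses pident).
#' @export
placeMarkers <- function(markers, assembly, seedLen = 21L, seedStride = 250L,
                         minReportPident = 80) {
  stopifnot(methods::is(markers, "MarkerSet"))
  if (is.character(assembly) && length(assembly) == 1L)
    assembly <- readSequences(assembly)
  if (length(assembly) == 0L) stop("assembly is empty")
  m <- markerLength(markers)
  if (seedLen > m) stop("seedLen must not exceed markerLen")
  mseqs <- markerSeqs(markers)
  nmk <- length(mseqs)
  if (nmk == 0L) return(.emptyAlignment())

  out <- vector("list", 2L * length(assembly))
  k <- 0L
  for (strand in c("+", "-")) {
    pats <- if (strand == "+") mseqs else Biostrings::reverseComplement(mseqs)
    seeds <- .markerSeeds(pats, seedLen, seedStride)
    if (nrow(seeds$tab) == 0L) next
    pdict <- Biostrings::PDict(seeds$set)
    for (i in seq_along(assembly)) {
      subj <- assembly[[i]]
      L <- length(subj)
      hits <- Biostrings::matchPDict(pdict, subj)
      st <- Biostrings::startIndex(hits)
      nh <- lengths(st)
      if (!sum(nh)) next
      idx <- rep.int(seq_len(nrow(seeds$tab)), nh)
      hit_start <- unlist(st, use.names = FALSE)
      cand <- unique(data.frame(
        marker = seeds$tab$marker[idx],
        offset = hit_start - seeds$tab$pos[idx] + 1L))
      cand <- cand[cand$offset >= 1L & cand$offset + m - 1L <= L, , drop = FALSE]
      if (!nrow(cand)) next
      rows_m <- lapply(split(cand$offset, cand$marker), sort)
      part <- vector("list", length(rows_m))
      for (j in seq_along(rows_m)) {
        mi <- as.integer(names(rows_m))[j]
        starts <- rows_m[[j]]
        nedit <- Biostrings::neditStartingAt(pats[[mi]], subj,
                                             starting.at = starts)
        pid <- (m - nedit) / m * 100
        keep <- pid >= minReportPident
        if (!any(keep)) next
        starts <- starts[keep]; nedit <- nedit[keep]; pid <- pid[keep]
        part[[j]] <- data.frame(
          query_id = names(mseqs)[mi],
          subject_id = names(assembly)[i],
          pident = pid, aln_len = m, mismatch = nedit, gapopen = 0L,
          q_start = 1L, q_end = m,
          s_start = if (strand == "+") starts else starts + m - 1L,
          s_end = if (strand == "+") starts + m - 1L else starts,
          evalue = 0, bitscore = as.numeric(m - nedit),
          stringsAsFactors = FALSE)
      }
      part <- part[!vapply(part, is.null, logical(1))]
      if (length(part)) {
        k <- k + 1L
        out[[k]] <- do.call(rbind, part)
      }
    }
  }
  out <- out[seq_len(k)]
  if (!length(out)) return(.emptyAlignment())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$query_id, res$subject_id, pmin(res$s_start, res$s_end)), ,
      drop = FALSE]
}

# Sample exact seeds along each marker; seeds containing N are unusable in
# a PDict and are dropped.
.markerSeeds <- function(pats, seedLen, seedStride) {
  m <- unique(Biostrings::width(pats))[1]
  pos <- sort(unique(c(seq.int(1L, m - seedLen + 1L, by = seedStride),
                       m - seedLen + 1L)))
  tab <- expand.grid(pos = as.integer(pos), marker = seq_along(pats))
  segs <- Biostrings::extractAt(
    pats,
    IRanges::IRangesList(lapply(seq_along(pats), function(i)
      IRanges::IRanges(start = pos, width = seedLen))))
  set <- unlist(segs, use.names = FALSE)
  has_n <- Biostrings::letterFrequency(set, "N")[, 1L] > 0
  # tab rows must align with unlisted seed order: marker-major
  tab <- tab[order(tab$marker, tab$pos), , drop = FALSE]
  list(set = set[!has_n], tab = tab[!has_n, , drop = FALSE])
}

.emptyAlignment <- function() {
  out <- data.frame(query_id = character(0), subject_id = character(0),
                    pident = numeric(0), aln_len = integer(0),
                    mismatch = integer(0), gapopen = integer(0),
                    q_start = integer(0), q_end = integer(0),
                    s_start = integer(0), s_end = integer(0),
                    evalue = numeric(0), bitscore = numeric(0),
                    stringsAsFactors = FALSE)
  out
}

#' Filter marker hits by percent identity with longest-scaffold exemption
#'
#' Keeps a hit if its percent identity reaches `minPident` ("close to 100%",
#' evidence of DNA-level identity between individuals of one species), or
#' unconditionally if it lies on an exempt scaffold — the per-chromosome
#' longest (primary) scaffolds, whose lower-identity hits may represent real
#' inter-individual variation rather than mismapping.
#'
#' @param rows alignment data.frame ([readAlignmentTable()] layout).
#' @param minPident identity threshold in percent (default 99; tolerates
#'   individual-level SNVs over a 2-kb marker).
#' @param exemptSubjects character vector of scaffold ids kept regardless of
#'   identity (typically `subject_id` of primary scaffolds from
#'   [assignScaffolds()]).
#' @return the kept rows.
#' @export
filterHits <- function(rows, minPident = 99, exemptSubjects = character(0)) {
  keep <- rows$pident >= minPident | rows$subject_id %in% exemptSubjects
  rows[keep, , drop = FALSE]
}

#' Select one placement per marker
#'
#' Reduces a (filtered) hit table to one `PlacedMarker` row per marker:
#' the best-scoring hit, where score is `bitscore` for imported alignments
#' or percent identity (then alignment length) for the built-in matcher.
#' Ties break deterministically by smallest subject start, then
#' lexicographic subject id. A marker whose runner-up score is within 2% of
#' the winner is flagged `ambiguous` (likely repeat-borne): ambiguous
#' markers are excluded from rearrangement calling but retained for dot
#' plots.
#'
#' @param rows filtered alignment data.frame.
#' @param scoreBy `"pident"` (built-in matcher; pident then aln_len) or
#'   `"bitscore"` (imported aligner output).
#' @return data.frame with one row per marker: `marker_id`, `ref_chrom`,
#'   `ref_start`, `subject_id`, `subject_start` (leftmost aligned base on
#'   the scaffold, 1-based), `strand`, `pident`, `aln_len`, `score`,
#'   `ambiguous`.
#' @export
bestHits <- function(rows, scoreBy = c("pident", "bitscore")) {
  scoreBy <- match.arg(scoreBy)
  if (nrow(rows) == 0L) return(.emptyPlacements())
  strand <- alignmentStrand(rows)
  sstart <- pmin(rows$s_start, rows$s_end)
  score <- if (scoreBy == "bitscore") rows$bitscore else rows$pident
  tie2 <- if (scoreBy == "bitscore") numeric(nrow(rows)) else rows$aln_len
  # order: per marker by decreasing score, decreasing secondary, then the
  # deterministic tie order (smallest subject_start, lexicographic subject)
  ord <- order(rows$query_id, -score, -tie2, sstart, rows$subject_id)
  o_q <- rows$query_id[ord]
  first <- !duplicated(o_q)
  best_i <- ord[first]
  # runner-up score per marker (second row in the per-marker order)
  nxt <- which(first) + 1L
  runner <- rep(NA_real_, length(best_i))
  valid <- nxt <= length(ord) & o_q[pmin(nxt, length(ord))] == o_q[which(first)]
  runner[valid] <- score[ord[nxt[valid]]]
  best_score <- score[best_i]
  ambiguous <- !is.na(runner) & runner >= best_score * 0.98
  info <- .parseMarkerId(rows$query_id[best_i])
  out <- data.frame(
    marker_id = rows$query_id[best_i],
    ref_chrom = info$chrom, ref_start = info$start,
    subject_id = rows$subject_id[best_i],
    subject_start = sstart[best_i],
    strand = strand[best_i],
    pident = rows$pident[best_i],
    aln_len = rows$aln_len[best_i],
    score = best_score,
    ambiguous = ambiguous,
    stringsAsFactors = FALSE)
  out <- out[order(out$ref_chrom, out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyPlacements <- function() {
  data.frame(marker_id = character(0), ref_chrom = character(0),
             ref_start = integer(0), subject_id = character(0),
             subject_start = integer(0), strand = character(0),
             pident = numeric(0), aln_len = integer(0), score = numeric(0),
             ambiguous = logical(0), stringsAsFactors = FALSE)
}
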