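# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
})

# Random sequence records for IO round trips.
randomRecords <- function(n, len = 50, seed = 1) {
  VirtualMarkers:::.withSeed(seed, {
    s <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T", "N"), len,
                   replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
            collapse = ""), character(1))
    out <- DNAStringSet(s)
    names(out) <- sprintf("rec%03d", seq_len(n))
    out
  })
}

# A small "world": random reference + its marker set.
makeWorld <- function(chromLengths = c(chrA = 6e5, chrB = 4e5),
                      spacing = 1e5, markerLen = 2000, seed = 11) {
  ref <- randomGenome(chromLengths, seed = seed)
  markers <- generateMarkers(ref, spacing = spacing, markerLen = markerLen)
  list(ref = ref, markers = markers,
       spacing = spacing, markerLen = markerLen,
       lengths = setNames(as.numeric(width(ref)), names(ref)))
}

# Map an assembly and reduce to placements with default filtering.
placeOn <- function(world, assembly, minPident = 99) {
  rows <- placeMarkers(world$markers, assembly)
  kept <- filterHits(rows, minPident = minPident)
  placed <- bestHits(kept)
  lens <- setNames(as.numeric(width(assembly)), names(assembly))
  assignments <- assignScaffolds(placed, lens)
  list(rows = rows, kept = kept, placed = placed, assignments = assignments)
}

# Independent O(n^2) LIS oracle (strictly increasing).
lisOracle <- function(x) {
  n <- length(x)
  if (n == 0) return(0L)
  dp <- rep(1L, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1))
    if (x[j] < x[i]) dp[i] <- max(dp[i], dp[j] + 1L)
  max(dp)
}

# Independent cumulative-sum oracle for N50/L50.
n50Oracle <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  cs <- cumsum(lens)
  k <- which(cs >= sum(lens) / 2)[1]
  list(n50 = lens[k], l50 = k)
}

# Brute-force best-hit oracle implementing the stated selection order:
# max score (pident then aln_len, or bitscore), ties by smallest leftmost
# subject coordinate then lexicographic subject id; ambiguous when the
# runner-up score is within 2% of the best.
bestHitOracle <- function(rows, scoreBy = "pident") {
  out <- lapply(split(rows, rows$query_id), function(r) {
    score <- if (scoreBy == "bitscore") r$bitscore else r$pident
    tie2 <- if (scoreBy == "bitscore") rep(0, nrow(r)) else r$aln_len
    sstart <- pmin(r$s_start, r$s_end)
    best <- NULL
    for (i in seq_len(nrow(r))) {
      if (is.null(best)) { best <- i; next }
      b <- best
      if (score[i] > score[b] ||
          (score[i] == score[b] && tie2[i] > tie2[b]) ||
          (score[i] == score[b] && tie2[i] == tie2[b] &&
           (sstart[i] < sstart[b] ||
            (sstart[i] == sstart[b] && r$subject_id[i] < r$subject_id[b]))))
        best <- i
    }
    runner <- if (nrow(r) > 1) max(score[-best]) else NA_real_
    data.frame(query_id = r$query_id[1], pick_subject = r$subject_id[best],
               pick_start = sstart[best], pick_score = score[best],
               ambiguous = !is.na(runner) && runner >= score[best] * 0.98,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$query_id), , drop = FALSE]
}

# Random synthetic alignment tables for predicate/argmax oracle tests.
randomAlignmentRows <- function(n, seed = 1, n_markers = 40, n_subjects = 6) {
  VirtualMarkers:::.withSeed(seed, {
    qs <- sprintf("chr%d_%d", sample(3, n, TRUE),
                  sample(n_markers, n, TRUE) * 1000 + 1)
    sstart <- sample.int(1e6, n)
    strand_minus <- runif(n) < 0.4
    len <- sample(500:2000, n, TRUE)
    data.frame(
      query_id = qs,
      subject_id = sprintf("scf%02d", sample(n_subjects, n, TRUE)),
      pident = round(runif(n, 80, 100), 2),
      aln_len = len, mismatch = 0L, gapopen = 0L,
      q_start = 1L, q_end = len,
      s_start = ifelse(strand_minus, sstart + len - 1L, sstart),
      s_end = ifelse(strand_minus, sstart, sstart + len - 1L),
      evalue = 0, bitscore = round(runif(n, 100, 4000), 1),
      stringsAsFactors = FALSE)
  })
}
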