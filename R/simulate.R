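# Synthetic-data generator: random genomes, planted rearrangements with
# ground truth, scaffold fragmentation with 100-N gaps, substitution noise,
# and long reads at specified coverage. Everything is seeded and
# deterministic so the whole pipeline is testable at desk scale.

.DNA <- c("A", "C", "G", "T")

#' Generate a random genome with specified GC content
#'
#' I.i.d. bases at the stated GC fraction (default 0.41, the human genome
#' average). Deterministic for a fixed seed.
#'
#' @param chromLengths named or unnamed numeric vector of chromosome
#'   lengths in bp; unnamed vectors get names `chr1, chr2, ...`.
#' @param gc GC fraction in [0, 1] (default 0.41).
#' @param seed integer RNG seed.
#' @return named `DNAStringSet`.
#' @export
randomGenome <- function(chromLengths, gc = 0.41, seed = 1L) {
  if (any(chromLengths < 1)) stop("chromosome lengths must be positive")
  nm <- names(chromLengths)
  if (is.null(nm)) nm <- paste0("chr", seq_along(chromLengths))
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codes <- utf8ToInt("ACGT")
  seqs <- .withSeed(seed, {
    vapply(chromLengths, function(L) {
      intToUtf8(sample(codes, L, replace = TRUE, prob = prob))
    }, character(1))
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nm
  out
}

#' Construct an edit specification table
#'
#' @param type `"inversion"`, `"translocation"` or `"deletion"` (vector ok).
#' @param chrom source chromosome.
#' @param start,end 1-based inclusive source interval.
#' @param dest_chrom,dest_pos destination for translocations (the excised
#'   segment is inserted before base `dest_pos` of `dest_chrom`, positions
#'   on the unedited frame); `NA` otherwise.
#' @return data.frame usable by [applyEdits()].
#' @export
editSpec <- function(type, chrom, start, end, dest_chrom = NA_character_,
                     dest_pos = NA_integer_) {
  df <- data.frame(type = type, chrom = chrom,
                   start = as.numeric(start), end = as.numeric(end),
                   dest_chrom = dest_chrom, dest_pos = as.numeric(dest_pos),
                   stringsAsFactors = FALSE)
  bad <- !df$type %in% c("inversion", "translocation", "deletion")
  if (any(bad)) stop("unknown edit type: ", paste(df$type[bad], collapse = ", "))
  if (any(df$start > df$end)) stop("edit start must be <= end")
  if (any(df$type == "translocation" &
          (is.na(df$dest_chrom) | is.na(df$dest_pos))))
    stop("translocations need dest_chrom and dest_pos")
  df
}

#' Apply rearrangement edits to a genome, recording ground truth
#'
#' Inversions replace the segment by its reverse complement in place;
#' deletions remove it; translocations excise it and insert it before
#' `dest_pos` on `dest_chrom`. Edits must be non-overlapping on the source;
#' all coordinates (including destinations) refer to the *unedited*
#' reference frame, which is also the frame of the recorded truth — so
#' reference-framed rearrangement calls compare to the truth directly.
#'
#' @param genome named `DNAStringSet`.
#' @param edits data.frame from [editSpec()].
#' @param seed,substitutionRate,breaks provenance fields stored in the
#'   returned truth set (not applied here; see [mutateGenome()] and
#'   [fragmentAndScaffold()]).
#' @return list with `genome` (edited `DNAStringSet`) and `truth` (list
#'   with `edits`, `seed`, `substitution_rate`, `breaks`; JSON-serializable
#'   via [writeTruth()]).
#' @export
applyEdits <- function(genome, edits, seed = NA_integer_,
                       substitutionRate = 0, breaks = list()) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (nrow(edits)) {
    if (any(!edits$chrom %in% names(genome)))
      stop("edit on unknown chromosome")
    for (ch in unique(edits$chrom)) {
      e <- edits[edits$chrom == ch, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      if (any(e$end > Biostrings::width(genome)[names(genome) == ch]))
        stop("edit extends past the end of ", ch)
      if (nrow(e) > 1L && any(e$start[-1L] <= e$end[-nrow(e)]))
        stop("overlapping edits on ", ch)
    }
  }
  chars <- as.character(genome)
  # Phase 1: in-place inversions (length preserving), excisions for
  # deletions/translocations, applied right-to-left per chromosome so
  # earlier source coordinates stay valid.
  excised <- list()
  for (ch in unique(edits$chrom)) {
    e <- edits[edits$chrom == ch, , drop = FALSE]
    e <- e[order(-e$start), , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      seg <- substr(chars[[ch]], e$start[i], e$end[i])
      if (e$type[i] == "inversion") {
        rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(seg)))
        chars[[ch]] <- paste0(substr(chars[[ch]], 1, e$start[i] - 1), rc,
                              substr(chars[[ch]], e$end[i] + 1,
                                     nchar(chars[[ch]])))
      } else {
        if (e$type[i] == "translocation")
          excised[[length(excised) + 1L]] <-
            list(seg = seg, dest_chrom = e$dest_chrom[i],
                 dest_pos = e$dest_pos[i])
        chars[[ch]] <- paste0(substr(chars[[ch]], 1, e$start[i] - 1),
                              substr(chars[[ch]], e$end[i] + 1,
                                     nchar(chars[[ch]])))
      }
    }
  }
  # Phase 2: insertions, right-to-left by destination position. Destination
  # chromosomes must not themselves carry length-changing edits upstream of
  # the insertion point (checked: dest coordinates are unedited-frame).
  if (length(excised)) {
    dest_chroms <- vapply(excised, `[[`, character(1), "dest_chrom")
    if (any(!dest_chroms %in% names(genome)))
      stop("translocation destination on unknown chromosome")
    changed <- unique(edits$chrom[edits$type %in% c("deletion", "translocation")])
    if (any(dest_chroms %in% changed))
      stop("translocation destination on a chromosome with length-changing edits; ",
           "destination coordinates would be ambiguous")
    ord <- order(-vapply(excised, `[[`, numeric(1), "dest_pos"))
    for (x in excised[ord]) {
      ch <- x$dest_chrom
      chars[[ch]] <- paste0(substr(chars[[ch]], 1, x$dest_pos - 1), x$seg,
                            substr(chars[[ch]], x$dest_pos,
                                   nchar(chars[[ch]])))
    }
  }
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- names(genome)
  list(genome = out,
       truth = list(edits = edits, seed = seed,
                    substitution_rate = substitutionRate, breaks = breaks))
}

#' Add i.i.d. substitution noise to a genome
#'
#' Each base is substituted with probability `rate` by one of the three
#' other bases, emulating inter-individual SNV divergence. N bases are
#' left untouched. Deterministic for a fixed seed.
#'
#' @param genome named `DNAStringSet`.
#' @param rate per-base substitution probability.
#' @param seed integer RNG seed.
#' @return mutated `DNAStringSet`.
#' @export
mutateGenome <- function(genome, rate, seed = 1L) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (rate == 0) return(genome)
  out <- .withSeed(seed, {
    seqs <- lapply(seq_along(genome), function(i) {
      x <- genome[[i]]
      L <- length(x)
      n <- stats::rbinom(1L, L, rate)
      if (n == 0L) return(x)
      at <- sort(sample.int(L, n))
      orig <- as.character(Biostrings::extractAt(
        x, IRanges::IRanges(at, width = 1L)))
      # substitute by a uniformly chosen *different* base; leave N alone
      shift <- sample.int(3L, n, replace = TRUE)
      idx <- match(orig, .DNA)
      new <- ifelse(is.na(idx), orig, .DNA[(idx - 1L + shift) %% 4L + 1L])
      Biostrings::replaceLetterAt(x, at, new)
    })
    Biostrings::DNAStringSet(seqs)
  })
  names(out) <- names(genome)
  out
}

#' Fragment chromosomes and rejoin with fixed-length N gaps
#'
#' Splits each chromosome at the given internal positions and rejoins the
#' pieces with runs of exactly `gapLen` N — the Hi-C scaffolding convention
#' of separating adjacent contigs by 100 N. The scaffold length is the
#' original length plus `gapLen` per break.
#'
#' @param genome named `DNAStringSet`.
#' @param breaks named list: chromosome -> integer positions; each break
#'   splits between position `b` and `b + 1`, so breaks must lie strictly
#'   inside the chromosome.
#' @param gapLen gap length in bp (default 100).
#' @return `DNAStringSet` of scaffolds (same names).
#' @export
fragmentAndScaffold <- function(genome, breaks, gapLen = 100L) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  chars <- as.character(genome)
  gap <- paste(rep("N", gapLen), collapse = "")
  for (ch in names(breaks)) {
    b <- sort(unique(as.integer(breaks[[ch]])))
    if (!length(b)) next
    if (!ch %in% names(genome)) stop("breaks for unknown chromosome ", ch)
    L <- nchar(chars[[ch]])
    if (any(b < 1L | b >= L))
      stop("break positions must be strictly inside ", ch)
    cuts <- c(0L, b, L)
    pieces <- substring(chars[[ch]], cuts[-length(cuts)] + 1L, cuts[-1L])
    chars[[ch]] <- paste(pieces, collapse = gap)
  }
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- names(genome)
  out
}

#' Simulate long reads at a target coverage
#'
#' Draws reads uniformly from the genome (both strands) with i.i.d.
#' substitution errors, until total bases reach `coverage * genome size`.
#' Read lengths are normal around `readLenMean` (sd 10% of the mean,
#' truncated to [500, chromosome length]). Substitution-only errors keep
#' every error-free read an exact substring of the genome (strand-aware).
#' Deterministic for a fixed seed.
#'
#' @param genome named `DNAStringSet`.
#' @param coverage target fold coverage (> 0).
#' @param readLenMean mean read length in bp (default 15,000, HiFi-like).
#' @param errorRate per-base substitution error probability (default 0.001).
#' @param seed integer RNG seed.
#' @param output optional FASTQ path; read names encode the true origin
#'   (`read{i} {chrom}:{start}-{end}/{strand}`).
#' @return invisibly, a `DNAStringSet` of reads (qualities written as
#'   constant Phred 40 when `output` is given).
#' @export
simulateReads <- function(genome, coverage, readLenMean = 15000,
                          errorRate = 0.001, seed = 1L, output = NULL) {
  if (coverage <= 0) stop("coverage must be positive")
  stopifnot(methods::is(genome, "DNAStringSet"))
  lens <- as.numeric(Biostrings::width(genome))
  G <- sum(lens)
  target <- coverage * G
  reads <- .withSeed(seed, {
    acc <- character(0); meta <- character(0); total <- 0
    while (total < target) {
      n_batch <- max(10L, ceiling((target - total) / readLenMean))
      ci <- sample.int(length(genome), n_batch, replace = TRUE,
                       prob = lens / G)
      rl <- pmin(pmax(round(stats::rnorm(n_batch, readLenMean,
                                         0.1 * readLenMean)), 500), lens[ci])
      st <- floor(stats::runif(n_batch) * (lens[ci] - rl + 1)) + 1
      rev <- stats::runif(n_batch) < 0.5
      for (j in seq_len(n_batch)) {
        if (total >= target) break
        s <- substr(as.character(genome[[ci[j]]]), st[j], st[j] + rl[j] - 1)
        if (rev[j])
          s <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
        if (errorRate > 0) {
          v <- strsplit(s, "", fixed = TRUE)[[1L]]
          hit <- which(stats::runif(length(v)) < errorRate & v != "N")
          if (length(hit)) {
            shift <- sample.int(3L, length(hit), replace = TRUE)
            v[hit] <- .DNA[(match(v[hit], .DNA) - 1L + shift) %% 4L + 1L]
            s <- paste(v, collapse = "")
          }
        }
        acc[length(acc) + 1L] <- s
        meta[length(meta) + 1L] <- sprintf(
          "%s:%d-%d/%s", names(genome)[ci[j]], st[j], st[j] + rl[j] - 1,
          if (rev[j]) "-" else "+")
        total <- total + rl[j]
      }
    }
    list(acc = acc, meta = meta)
  })
  out <- Biostrings::DNAStringSet(reads$acc)
  names(out) <- sprintf("read%06d %s", seq_along(out), reads$meta)
  if (!is.null(output)) {
    quals <- Biostrings::BStringSet(
      vapply(Biostrings::width(out),
             function(w) paste(rep("I", w), collapse = ""), character(1)))
    Biostrings::writeXStringSet(out, output, format = "fastq",
                                qualities = quals,
                                compress = grepl("\\.gz$", output))
  }
  invisible(out)
}

#' Write / read a simulation truth set as JSON
#'
#' @param truth truth list from [applyEdits()].
#' @param path JSON path.
#' @return `path` invisibly / the truth list.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$edits) && length(x$edits)) {
    x$edits <- as.data.frame(x$edits, stringsAsFactors = FALSE)
  } else {
    x$edits <- editSpec(character(0), character(0), numeric(0), numeric(0))
  }
  if (is.null(x$breaks)) x$breaks <- list()
  x
}
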