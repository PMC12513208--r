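# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded operations do not perturb the caller's
#' random stream.
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
.withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic TSV writers: fixed column order, no quoting, no row names,
# so identical inputs give byte-identical files.
.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.readTsv <- function(path, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, colClasses = colClasses,
                    check.names = FALSE)
}

#' Length of the longest strictly increasing subsequence
#'
#' Patience-sorting implementation, O(n log n). Values must be numeric;
#' ties never extend a subsequence (strict monotonicity).
#' @param x numeric vector.
#' @return integer length of the LIS (0 for empty input).
#' @keywords internal
#' @noRd
.lisLength <- function(x) {
  tails <- numeric(0)
  for (v in x) {
    # first tail >= v gets replaced; strictly-less tails stay
    j <- findInterval(v - 0.5, tails) + 1L
    if (j > length(tails)) tails <- c(tails, v) else tails[j] <- v
  }
  length(tails)
}

# Minimal union-find over 1..n for single-linkage clustering.
.unionFind <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Parse marker ids of the form "{chrom}_{start1}"; chrom may itself
# contain underscores, so split at the last one.
.parseMarkerId <- function(ids) {
  start <- as.integer(sub("^.*_([0-9]+)$", "\\1", ids))
  chrom <- sub("_[0-9]+$", "", ids)
  if (anyNA(start)) stop("malformed marker id(s): ",
                         paste(utils::head(ids[is.na(start)], 3), collapse = ", "))
  data.frame(id = ids, chrom = chrom, start = start,
             stringsAsFactors = FALSE)
}

# 1-based inclusive region string, Table-2 style ("chr8:8200001-12100001").
.regionString <- function(chrom, start1, end1) {
  sprintf("%s:%d-%d", chrom, as.integer(start1), as.integer(end1))
}
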