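#' MarkerSet: uniformly spaced virtual markers from a reference genome
#'
#' Holds the marker sequences together with their reference coordinates and
#' the grid geometry that generated them. Markers are short (`markerLen` bp)
#' windows extracted every `spacing` bp along each reference chromosome,
#' starting at position 1, and act as alignment probes against assemblies.
#'
#' @slot seqs [Biostrings::DNAStringSet] of marker sequences; names are the
#'   marker ids `"{chrom}_{start1}"`.
#' @slot chrom character vector, source chromosome per marker.
#' @slot start integer vector, 1-based start of each marker on its chromosome;
#'   always of the form `k * spacing + 1`.
#' @slot spacing single number, grid spacing in bp.
#' @slot markerLen single number, marker length in bp.
#' @slot maxAmbiguousFrac single number, maximum tolerated fraction of N in a
#'   marker window; windows above it were skipped at generation time.
#'
#' @seealso [generateMarkers()], [writeMarkers()], [readMarkers()]
#' @export
setClass("MarkerSet",
  representation(
    seqs = "DNAStringSet",
    chrom = "character",
    start = "integer",
    spacing = "numeric",
    markerLen = "numeric",
    maxAmbiguousFrac = "numeric"
  )
)

setValidity("MarkerSet", function(object) {
  msg <- character(0)
  n <- length(object@seqs)
  if (length(object@chrom) != n || length(object@start) != n)
    msg <- c(msg, "chrom/start must have one entry per marker sequence")
  if (object@markerLen >= object@spacing)
    msg <- c(msg, "markerLen must be smaller than spacing")
  if (object@spacing < 1000)
    msg <- c(msg, "spacing must be >= 1000 bp")
  if (object@maxAmbiguousFrac < 0 || object@maxAmbiguousFrac > 1)
    msg <- c(msg, "maxAmbiguousFrac must be in [0, 1]")
  if (n > 0) {
    if (any(Biostrings::width(object@seqs) != object@markerLen))
      msg <- c(msg, "all marker sequences must have width markerLen")
    if (any((object@start - 1L) %% object@spacing != 0))
      msg <- c(msg, "marker starts must lie on the 1-anchored grid (k*spacing + 1)")
    ids <- paste0(object@chrom, "_", object@start)
    if (anyDuplicated(ids))
      msg <- c(msg, "marker ids must be unique")
    if (!identical(names(object@seqs), ids))
      msg <- c(msg, "sequence names must equal '{chrom}_{start}' ids")
    ord <- order(object@chrom, object@start)
    byc <- split(object@start, object@chrom)
    if (any(vapply(byc, function(s) is.unsorted(s, strictly = TRUE), logical(1))))
      msg <- c(msg, "markers must be strictly ordered by start within a chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' AssemblyStats: contiguity statistics of a scaffold set
#'
#' @slot nScaffolds integer, number of scaffolds.
#' @slot totalBp numeric, total assembly size in bp.
#' @slot n50 numeric, scaffold N50 in bp.
#' @slot l50 integer, scaffold L50 (rank of the N50 scaffold).
#' @slot nAmbiguous numeric, total count of N bases.
#' @slot longest numeric, length of the longest scaffold in bp.
#'
#' @seealso [scaffoldStats()]
#' @export
setClass("AssemblyStats",
  representation(
    nScaffolds = "integer",
    totalBp = "numeric",
    n50 = "numeric",
    l50 = "integer",
    nAmbiguous = "numeric",
    longest = "numeric"
  )
)

setValidity("AssemblyStats", function(object) {
  msg <- character(0)
  if (object@n50 > object@longest) msg <- c(msg, "N50 cannot exceed the longest scaffold")
  if (object@l50 < 1L || object@l50 > object@nScaffolds)
    msg <- c(msg, "L50 must be between 1 and the number of scaffolds")
  if (object@nAmbiguous > object@totalBp)
    msg <- c(msg, "ambiguous-base count cannot exceed total size")
  if (length(msg)) msg else TRUE
})
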