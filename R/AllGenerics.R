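# Accessor generics for the package's S4 classes.

#' @rdname MarkerSet-class
#' @param object,x a `MarkerSet` or `AssemblyStats` object.
#' @export
setGeneric("markerSeqs", function(object) standardGeneric("markerSeqs"))

#' @rdname MarkerSet-class
#' @export
setGeneric("markerTable", function(object) standardGeneric("markerTable"))

#' @rdname MarkerSet-class
#' @export
setGeneric("markerSpacing", function(object) standardGeneric("markerSpacing"))

#' @rdname MarkerSet-class
#' @export
setGeneric("markerLength", function(object) standardGeneric("markerLength"))

#' @rdname AssemblyStats-class
#' @export
setGeneric("n50", function(object) standardGeneric("n50"))

#' @rdname AssemblyStats-class
#' @export
setGeneric("l50", function(object) standardGeneric("l50"))

#' Extract sequences of marker ids
#' @name MarkerSet-accessors
NULL

#' @describeIn MarkerSet-class marker sequences as a `DNAStringSet`.
setMethod("markerSeqs", "MarkerSet", function(object) object@seqs)

#' @describeIn MarkerSet-class data.frame of `id`, `chrom`, `start` (1-based).
setMethod("markerTable", "MarkerSet", function(object) {
  data.frame(id = names(object@seqs), chrom = object@chrom,
             start = object@start, stringsAsFactors = FALSE)
})

#' @describeIn MarkerSet-class grid spacing in bp.
setMethod("markerSpacing", "MarkerSet", function(object) object@spacing)

#' @describeIn MarkerSet-class marker length in bp.
setMethod("markerLength", "MarkerSet", function(object) object@markerLen)

#' @describeIn MarkerSet-class number of markers.
#' @export
setMethod("length", "MarkerSet", function(x) length(x@seqs))

setMethod("show", "MarkerSet", function(object) {
  cat("MarkerSet with", length(object@seqs), "markers on",
      length(unique(object@chrom)), "chromosome(s)\n")
  cat("  spacing:", format(object@spacing, big.mark = ","), "bp;",
      "marker length:", format(object@markerLen, big.mark = ","), "bp;",
      "max N fraction:", object@maxAmbiguousFrac, "\n")
})

#' @describeIn AssemblyStats-class scaffold N50 in bp.
setMethod("n50", "AssemblyStats", function(object) object@n50)

#' @describeIn AssemblyStats-class scaffold L50.
setMethod("l50", "AssemblyStats", function(object) object@l50)

setMethod("show", "AssemblyStats", function(object) {
  cat("AssemblyStats:", object@nScaffolds, "scaffolds,",
      format(object@totalBp, big.mark = ","), "bp total\n")
  cat("  N50:", format(object@n50, big.mark = ","), "bp;  L50:", object@l50,
      ";  longest:", format(object@longest, big.mark = ","), "bp;  Ns:",
      format(object@nAmbiguous, big.mark = ","), "\n")
})

#' Coerce AssemblyStats to a one-row data.frame
#'
#' @param x an `AssemblyStats` object.
#' @param ... unused.
#' @return one-row data.frame with columns `n_scaffolds`, `total_bp`, `N50`,
#'   `L50`, `n_ambiguous`, `longest`.
#' @method as.data.frame AssemblyStats
#' @export
as.data.frame.AssemblyStats <- function(x, ...) {
  data.frame(n_scaffolds = x@nScaffolds, total_bp = x@totalBp,
             N50 = x@n50, L50 = x@l50, n_ambiguous = x@nAmbiguous,
             longest = x@longest)
}
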