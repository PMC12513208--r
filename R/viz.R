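# Dot-plot construction: marker reference coordinate (x) against placed
# assembly coordinate (y). The points table is the canonical artifact;
# rendered images are derived views.

#' Build dot-plot points from kept marker hits
#'
#' One point per kept hit (all hits, not only best hits, so repeated or
#' ambiguous loci remain visible): x is the marker start on the reference,
#' y the hit start on its scaffold after per-scaffold orientation
#' normalization (a wholly reverse-complemented scaffold still plots on the
#' diagonal; an internal inversion plots as an anti-diagonal run). Points
#' carry the hit strand for coloring.
#'
#' @param hits filtered alignment data.frame ([filterHits()] output).
#' @param assignments data.frame from [assignScaffolds()].
#' @param assemblyLabel label attached to every point.
#' @return data.frame with columns `assembly_label`, `ref_chrom`,
#'   `ref_start`, `subject_id`, `subject_pos`, `strand`, `y_offset`.
#' @export
dotplotPoints <- function(hits, assignments, assemblyLabel = "assembly") {
  if (nrow(hits) == 0L) {
    return(data.frame(assembly_label = character(0), ref_chrom = character(0),
                      ref_start = integer(0), subject_id = character(0),
                      subject_pos = numeric(0), strand = character(0),
                      y_offset = numeric(0), stringsAsFactors = FALSE))
  }
  info <- .parseMarkerId(hits$query_id)
  p <- data.frame(
    marker_id = hits$query_id, ref_chrom = info$chrom,
    ref_start = info$start, subject_id = hits$subject_id,
    subject_start = pmin(hits$s_start, hits$s_end),
    strand = alignmentStrand(hits), aln_len = hits$aln_len,
    ambiguous = FALSE, stringsAsFactors = FALSE)
  p <- .normalizePlacements(p, assignments)
  out <- data.frame(
    assembly_label = assemblyLabel, ref_chrom = p$ref_chrom,
    ref_start = p$ref_start, subject_id = p$subject_id,
    subject_pos = p$norm_pos, strand = p$norm_strand,
    y_offset = 0, stringsAsFactors = FALSE)
  out[order(out$ref_chrom, out$ref_start, out$subject_id, out$subject_pos), ,
      drop = FALSE]
}

#' Stack dot-plot point sets from several assemblies
#'
#' Shifts each successive assembly's y values by one further `yOffset`
#' (default 5 Mb) so genomes do not overlap on the diagonal when plotted
#' together.
#'
#' @param pointsList list of [dotplotPoints()] tables, bottom to top.
#' @param yOffset vertical shift between assemblies in bp (default 5e6).
#' @return combined points table with `y_offset` filled in.
#' @export
stackDotplots <- function(pointsList, yOffset = 5e6) {
  stopifnot(length(pointsList) >= 1L)
  for (i in seq_along(pointsList))
    pointsList[[i]]$y_offset <- (i - 1) * yOffset
  do.call(rbind, pointsList)
}

#' Render a dot plot
#'
#' Scatter of `ref_start` against `subject_pos + y_offset`, one panel per
#' reference chromosome, colored by strand (forward runs are diagonal,
#' reverse runs anti-diagonal). Rendering never drops or adds points: the
#' plotted data is exactly the input table.
#'
#' @param points table from [dotplotPoints()] / [stackDotplots()].
#' @param pointSize point size (default 0.4).
#' @return a `ggplot` object.
#' @export
renderDotplot <- function(points, pointSize = 0.4) {
  ggplot2::ggplot(points, ggplot2::aes(
    x = .data$ref_start, y = .data$subject_pos + .data$y_offset,
    colour = .data$strand)) +
    ggplot2::geom_point(size = pointSize) +
    ggplot2::facet_wrap(~ref_chrom, scales = "free") +
    ggplot2::scale_colour_manual(values = c(`+` = "#2166ac", `-` = "#b2182b")) +
    ggplot2::labs(x = "reference position (bp)",
                  y = "assembly position (bp)", colour = "strand") +
    ggplot2::theme_bw()
}

#' Write dot-plot points as TSV
#'
#' @param points table from [dotplotPoints()] / [stackDotplots()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeDotplotPoints <- function(points, path) .writeTsv(points, path)
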