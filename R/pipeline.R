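# End-to-end orchestration: markers -> map/import -> filter -> assign ->
# blocks -> call -> dot-plot points -> genotype matrix, with a serialized
# run manifest. The pipeline is a pure function of (inputs, config):
# identical configs give byte-identical TSV outputs.

#' Build a run configuration
#'
#' @param reference reference genome: FASTA path or named `DNAStringSet`.
#' @param assemblies named list of assemblies (FASTA paths or
#'   `DNAStringSet`s); names are the assembly labels.
#' @param spacing,markerLen,maxAmbiguousFrac marker grid geometry
#'   (see [generateMarkers()]).
#' @param minPident identity filter threshold ([filterHits()]).
#' @param minMarkers minimum markers per rearrangement call.
#' @param gapTol block-chaining gap tolerance in grid steps.
#' @param mergeOverlap reciprocal-overlap threshold for the genotype matrix.
#' @param seedLen built-in matcher seed length.
#' @param alignments optional named list (label -> alignment file) of
#'   precomputed alignments; entries may be `list(path=, dialect=)` or a
#'   path (dialect `"blast6"`). Assemblies with no entry use the built-in
#'   matcher.
#' @param outDir output directory (created if missing).
#' @return config list for [runCompare()].
#' @export
runConfig <- function(reference, assemblies, outDir,
                      spacing = 1e6, markerLen = 2000,
                      maxAmbiguousFrac = 0.2, minPident = 99,
                      minMarkers = 2, gapTol = 3, mergeOverlap = 0.8,
                      seedLen = 21L, alignments = list()) {
  if (is.null(names(assemblies)) || any(!nzchar(names(assemblies))))
    stop("assemblies must be a named list (names are assembly labels)")
  for (p in c(list(reference), assemblies))
    if (is.character(p) && !file.exists(p)) stop("missing input: ", p)
  for (a in alignments) {
    p <- if (is.list(a)) a$path else a
    if (!file.exists(p)) stop("missing alignment file: ", p)
  }
  list(reference = reference, assemblies = assemblies, outDir = outDir,
       spacing = spacing, markerLen = markerLen,
       maxAmbiguousFrac = maxAmbiguousFrac, minPident = minPident,
       minMarkers = minMarkers, gapTol = gapTol,
       mergeOverlap = mergeOverlap, seedLen = seedLen,
       alignments = alignments)
}

#' Run the full marker-based comparison pipeline
#'
#' For each assembly: place markers (built-in matcher, or imported
#' alignments), apply the two-pass identity filter (pass 1 filters at
#' `minPident` and assigns scaffolds; pass 2 re-admits sub-threshold hits
#' on each chromosome's primary scaffold — the longest-scaffold exemption),
#' select best hits, segment collinear blocks, call inversions and
#' translocations, and compute linearity metrics and dot-plot points.
#' Calls from all assemblies are then merged into a genotype matrix.
#'
#' Outputs under `config$outDir`: per-assembly
#' `<label>.{hits,placements,assignments,blocks,metrics,dotplot}.tsv` and
#' `<label>.calls.tsv`, plus `genotype_matrix.tsv`, stacked
#' `dotplot_points.tsv` and `manifest.json`.
#'
#' @param config list from [runConfig()].
#' @return invisibly, a list with all intermediate results
#'   (`markers`, per-assembly list `per_assembly`, `calls`, `genotype`).
#' @export
runCompare <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  ref <- config$reference
  if (is.character(ref)) ref <- readSequences(ref)
  markers <- generateMarkers(ref, spacing = config$spacing,
                             markerLen = config$markerLen,
                             maxAmbiguousFrac = config$maxAmbiguousFrac)
  writeMarkers(markers, file.path(config$outDir, "markers.fa"))
  labels <- names(config$assemblies)
  per <- vector("list", length(labels)); names(per) <- labels
  all_calls <- list(); all_points <- list()
  for (lab in labels) {
    asm <- config$assemblies[[lab]]
    if (is.character(asm)) asm <- readSequences(asm)
    aln_spec <- config$alignments[[lab]]
    if (!is.null(aln_spec)) {
      path <- if (is.list(aln_spec)) aln_spec$path else aln_spec
      dialect <- if (is.list(aln_spec) && !is.null(aln_spec$dialect))
        aln_spec$dialect else "blast6"
      rows <- readAlignmentTable(path, dialect)
      scoreBy <- "bitscore"
    } else {
      rows <- placeMarkers(markers, asm, seedLen = config$seedLen)
      scoreBy <- "pident"
    }
    asm_len <- stats::setNames(as.numeric(Biostrings::width(asm)), names(asm))
    # pass 1: strict identity filter, assign scaffolds, find primaries
    kept1 <- filterHits(rows, minPident = config$minPident)
    if (nrow(kept1) == 0L) {
      message("assembly '", lab, "': no hits pass the identity filter")
      next
    }
    placed1 <- bestHits(kept1, scoreBy = scoreBy)
    assign1 <- assignScaffolds(placed1, asm_len)
    exempt <- assign1$subject_id[assign1$is_primary]
    # pass 2: re-admit sub-threshold hits on primary scaffolds
    kept <- filterHits(rows, minPident = config$minPident,
                       exemptSubjects = exempt)
    placed <- bestHits(kept, scoreBy = scoreBy)
    assignments <- assignScaffolds(placed, asm_len)
    blocks <- segmentBlocks(placed, assignments, spacing = config$spacing,
                            gapTol = config$gapTol)
    inv <- callInversions(blocks, spacing = config$spacing,
                          minMarkers = config$minMarkers,
                          assemblyLabel = lab)
    trl <- callTranslocations(placed, assignments, spacing = config$spacing,
                              minMarkers = config$minMarkers,
                              assemblyLabel = lab)
    # disjoint seqlevels between the two call sets are expected, not a problem
    calls <- suppressWarnings(c(inv, trl))
    metrics <- linearityMetrics(placed, assignments, markers)
    points <- dotplotPoints(kept, assignments, assemblyLabel = lab)
    n_drop <- nrow(rows) - nrow(kept)
    message(sprintf(
      "assembly '%s': %d hits (%d dropped by filter), %d markers placed (%d ambiguous), %d blocks, %d calls",
      lab, nrow(rows), n_drop, nrow(placed), sum(placed$ambiguous),
      nrow(blocks), length(calls)))
    od <- function(x) file.path(config$outDir, paste0(lab, ".", x, ".tsv"))
    .writeTsv(rows, od("hits"))
    .writeTsv(placed, od("placements"))
    .writeTsv(assignments, od("assignments"))
    .writeTsv(blocks, od("blocks"))
    .writeTsv(metrics, od("metrics"))
    writeCalls(calls, od("calls"))
    writeDotplotPoints(points, od("dotplot"))
    per[[lab]] <- list(hits = rows, placements = placed,
                       assignments = assignments, blocks = blocks,
                       calls = calls, metrics = metrics, points = points)
    all_calls[[lab]] <- calls
    all_points[[lab]] <- points
  }
  calls <- if (length(all_calls))
    suppressWarnings(do.call(c, unname(all_calls))) else .emptyCalls()
  geno <- genotypeMatrix(calls, assemblies = labels,
                         reciprocalOverlap = config$mergeOverlap)
  gm <- data.frame(locus = rownames(geno$matrix),
                   type = if (length(geno$loci))
                     as.character(S4Vectors::mcols(geno$loci)$type)
                   else character(0),
                   geno$matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTsv(gm, file.path(config$outDir, "genotype_matrix.tsv"))
  if (length(all_points))
    writeDotplotPoints(stackDotplots(all_points),
                       file.path(config$outDir, "dotplot_points.tsv"))
  manifest <- list(
    package = "VirtualMarkers",
    version = as.character(utils::packageVersion("VirtualMarkers")),
    parameters = config[c("spacing", "markerLen", "maxAmbiguousFrac",
                          "minPident", "minMarkers", "gapTol",
                          "mergeOverlap", "seedLen")],
    assemblies = labels,
    n_markers = length(markers))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(markers = markers, per_assembly = per, calls = calls,
                 genotype = geno))
}
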