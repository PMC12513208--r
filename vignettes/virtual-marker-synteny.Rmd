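---
title: "Virtual-marker synteny validation and large inversion detection"
author: "VirtualMarkers package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-marker synteny validation and large inversion detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VirtualMarkers)
suppressPackageStartupMessages(library(Biostrings))
```

## The method

Chromosome-level assemblies of individuals from the same species are now
routinely produced from long reads plus Hi-C scaffolding. Validating such an
assembly — and comparing it against other individuals — is usually done
through gene-level synteny, but protein-coding sequence covers a small
fraction of most genomes. This package implements DNA-level validation via
**virtual markers**: short probe sequences (default 2 kb) extracted from a
reference genome at fixed intervals (default every 1 Mb; 100 kb for the
high-resolution variant), aligned back to each assembly, and interpreted
through the order and orientation of their placements.

The core logic is a chain of small, auditable steps:

1. **Marker generation** (`generateMarkers`). Windows of length $m$ start at
   reference positions $1, s+1, 2s+1, \dots$ where $s$ is the spacing. The
   grid is anchored at 1, so every marker start — and every breakpoint
   reported downstream — has the form $ks + 1$. Windows with more than 20% N
   are skipped: they sit over assembly gaps and cannot align.
2. **Placement** (`placeMarkers`, or imported blastn outfmt-6 / PAF tables
   via `readAlignmentTable`). The built-in matcher samples exact 21-mers
   along each marker, locates them on both strands of every scaffold, and
   scores each implied locus by ungapped full-length comparison;
   identity is $\mathrm{matches}/m \times 100$.
3. **Filtering** (`filterHits`). Hits with identity $\ge$ 99% are kept —
   over a 2-kb probe this tolerates the SNV density expected between
   individuals of one species. Hits on each chromosome's longest assigned
   scaffold are kept *regardless* of identity, because divergent loci on the
   main chromosomal scaffold can be genuine inter-individual variation. The
   pipeline applies these two rules in two passes: a strict pass first
   assigns scaffolds and identifies the longest (primary) scaffold per
   chromosome, then the exemption re-admits sub-threshold hits on it.
4. **Best-hit selection** (`bestHits`). One placement per marker: highest
   bitscore (imported) or identity-then-length (built-in), ties broken by
   smallest subject coordinate, then lexicographic scaffold id. When the
   runner-up scores within 2% of the winner the marker is flagged
   *ambiguous* — a repeat signature — and excluded from rearrangement
   calling, though it still appears in dot plots.
5. **Assignment and orientation** (`assignScaffolds`). Scaffolds are
   assigned to chromosomes by majority vote of their placed markers, and
   given the majority strand as their orientation. Hi-C scaffolds have
   arbitrary strand, so all downstream signs are relative to this dominant
   orientation: a wholly reverse-complemented scaffold is *not* an
   inversion.
6. **Block segmentation** (`segmentBlocks`). Markers are walked in reference
   grid order and chained while they stay on one scaffold, keep one
   normalized strand, and jump consistently
   ($|\Delta y - \mathrm{sign}\cdot\Delta x| \le g\,s$, gap tolerance
   $g = 3$ grid steps, so isolated failed markers do not fragment blocks).
   Sign $+1$ blocks are dot-plot diagonals; sign $-1$ blocks are
   anti-diagonals.
7. **Calling** (`callInversions`, `callTranslocations`). Reverse blocks with
   at least `minMarkers` (default 2) supporting markers become inversion
   calls; runs of markers landing on a scaffold assigned to a different
   chromosome become translocation calls. Reported intervals are snapped to
   the grid — `[first marker start, last marker start + s]` — so the true
   breakpoint lies within one grid step of each reported endpoint, and
   coordinates are printed 1-based inclusive (`chr8:8200001-12100001`
   style).

## Detection limits

A rearrangement is *guaranteed* callable only if it must contain
`minMarkers` whole markers at every possible placement offset.
`guaranteedDetectableLength` computes that bound by brute force over all
integer offsets (the closed form $k s + m - 1$ is cross-checked against the
brute force in the test suite):

```{r limits}
guaranteedDetectableLength(1e6, 2000, 2)  # 1-Mb grid: ~2 Mb
guaranteedDetectableLength(1e5, 2000, 2)  # 100-kb grid: ~200 kb
```

Shorter events may still be called when they happen to straddle markers,
but only these lengths are guaranteed. This is why a 1-Mb grid validates
chromosome-scale linearity cheaply while the 100-kb grid is needed to see
events of a few hundred kb.

## The synthetic world

The simulator exists so that every stage can be validated against planted
truth at desk scale. Its defaults are fixed once and state what the
generated data emulate:

* `randomGenome`: i.i.d. bases, GC 0.41 (the human average). Real genomes
  have repeats, segmental duplications and centromeres; i.i.d. sequence has
  essentially unique 21-mers, so the simulator exercises coordinate
  bookkeeping and calling logic, *not* repeat resolution. A green recovery
  test therefore establishes correctness of the machinery, not performance
  on repeat-rich DNA — ambiguity flagging is the package's hedge there.
* `applyEdits`: inversions (in-place reverse complement), deletions and
  translocations, non-overlapping on the source, with truth recorded on the
  unedited reference frame so reference-framed calls compare directly.
* `mutateGenome`: substitution noise at 0.1% by default — the scale of
  SNV divergence between two individuals of one species, and comfortably
  inside the 99% identity filter for 2-kb probes (expected 2 mismatches per
  marker). Indels are deliberately absent: the built-in matcher is
  substitution-only and exactly testable; indel realism is delegated to
  external aligners whose output can be imported.
* `fragmentAndScaffold`: contig joins of exactly 100 N, the Hi-C
  scaffolding convention, so N-gap handling is representative.
* `simulateReads`: uniform reads, mean 15 kb (HiFi-like), substitution
  errors only, drawn until total bases reach coverage × genome size.

## Numerical and design choices

* **Coordinates.** All internal coordinates are 1-based inclusive, the
  native Bioconductor convention (`IRanges`/`GRanges`); BED-like output is
  converted to 0-based half-open at the file boundary, and report strings
  are 1-based. Keeping the container convention internally avoids a
  translation layer in every function.
* **Ambiguity margin.** The 2% runner-up margin is a repeat guard: on
  unique i.i.d. sequence it never fires; on real data it suppresses calls
  from near-identical paralogous placements.
* **`minMarkers = 2`.** Matches the detection limits above; single-marker
  evidence is indistinguishable from a mismapped probe. Raise to 3 for
  noisy imported alignments.
* **Longest-scaffold exemption order.** The identity filter and the
  exemption are applied strict-first, exempt-second (two passes), since the
  exemption needs to know which scaffold is primary; the alternative order
  would let low-identity hits vote on scaffold assignment.
* **Tie-breaks.** Every tie in best-hit selection, chromosome voting and
  block segmentation resolves deterministically (coordinate, then
  lexicographic), making the whole pipeline a pure function of its inputs —
  repeated runs are byte-identical.
* **L50 convention.** Cumulative length $\ge$ half the total (not $>$),
  under which a complete human assembly of 23 chromosome-scale scaffolds
  yields L50 8–9.
* **Degenerate inputs.** Chromosomes shorter than a marker warn and are
  skipped; markers with no seed simply produce no hits; empty call sets
  write header-only files; subsampling beyond the available bases returns
  everything with a warning.

## A worked desk-scale example

```{r example}
ref <- randomGenome(c(chr1 = 8e6), seed = 1)
sim <- applyEdits(ref, editSpec("inversion", "chr1", 3000001, 5500000))
asm <- fragmentAndScaffold(mutateGenome(sim$genome, 0.001, seed = 2),
                           list(chr1 = 6e6))
names(asm) <- "scaffold_1"

out <- file.path(tempdir(), "vmk-demo")
cfg <- runConfig(ref, list(ind1 = asm), outDir = out, spacing = 1e5)
res <- runCompare(cfg)
callsToTable(res$calls)[, c("region", "type", "n_markers")]
```

The planted 2.5-Mb inversion at chr1:3,000,001–5,500,000 is recovered with
both breakpoints inside one 100-kb grid step of the truth.

## Known limitations

* Marker placement is full-length and ungapped; assemblies with large
  indels inside a marker window need imported aligner output.
* Repeat-dense references produce many ambiguous markers; the package
  flags rather than resolves them (no uniqueness screening at generation
  time).
* Centromeric behaviour of real genomes — clustered low-identity,
  ambiguous placements — is reported through flags and low collinearity,
  not modelled.
* Collinearity is quantified as the longest strictly monotone subsequence
  of primary-scaffold placements divided by placed markers; it is this
  package's quantification of "dots on the diagonal" and is not calibrated
  against any published scalar.
* The genotype matrix merges loci by reciprocal overlap (default 0.8); a
  locus fragmented differently in two assemblies may split where visual
  inspection would merge it.
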