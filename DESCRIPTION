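Package: VirtualMarkers
Title: Virtual-Marker Comparative Genomics and Large Inversion Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates uniformly spaced short DNA markers ("virtual markers")
    from a reference genome, places them on one or more assemblies (built-in
    exact-seed matcher or imported BLAST tabular / PAF alignments), validates
    DNA-level linearity via dot plots and collinearity statistics, and calls
    large inversions and translocations with grid-snapped breakpoints.
    Includes assembly contiguity statistics (N50/L50), seeded long-read
    subsampling for coverage titration, and a synthetic genome rearrangement
    simulator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    ggplot2
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
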