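# Inversion/translocation calling, detection limits, span support,
# genotype matrices.

# Run the full desk-scale calling pipeline against an assembly.
callOn <- function(world, assembly, minMarkers = 2, label = "asm") {
  res <- placeOn(world, assembly)
  blocks <- segmentBlocks(res$placed, res$assignments,
                          spacing = world$spacing)
  c(callInversions(blocks, spacing = world$spacing, minMarkers = minMarkers,
                   assemblyLabel = label),
    callTranslocations(res$placed, res$assignments, spacing = world$spacing,
                       minMarkers = minMarkers, assemblyLabel = label))
}

test_that("a planted 3-Mb inversion is called with grid-resolution breakpoints", {
  w <- makeWorld(c(chrA = 12e6), spacing = 1e5, seed = 51)
  truth_start <- 4000001; truth_end <- 7000000
  sim <- applyEdits(w$ref, editSpec("inversion", "chrA", truth_start, truth_end))
  asm <- sim$genome
  names(asm) <- "scaffold_1"
  calls <- callOn(w, asm)
  inv <- calls[mcols(calls)$type == "inversion"]
  expect_equal(length(inv), 1L)
  expect_lte(abs(start(inv) - truth_start), w$spacing)
  expect_lte(abs(end(inv) - truth_end), w$spacing)
  expect_true((start(inv) - 1) %% w$spacing == 0)  # grid-snapped
  expect_gte(mcols(inv)$n_markers, 2L)
})

test_that("unedited and involution assemblies yield zero calls", {
  w <- makeWorld(c(chrA = 3e6, chrB = 2e6), spacing = 1e5, seed = 52)
  expect_equal(length(callOn(w, w$ref)), 0L)
  # involution: the same inversion applied twice restores the genome
  e <- editSpec("inversion", "chrA", 500001, 1500000)
  g1 <- applyEdits(w$ref, e)$genome
  g2 <- applyEdits(g1, e)$genome
  expect_identical(as.character(g2), as.character(w$ref))
  expect_equal(length(callOn(w, g2)), 0L)
})

test_that("an inversion holding a single marker stays below the calling threshold", {
  # 1.5-Mb inversion at 1-Mb spacing, offset so exactly one marker
  # (2,000,001) lies fully inside: below minMarkers = 2, hence no call --
  # the geometry behind the ~2-Mb sensitivity floor of a 1-Mb marker grid.
  w <- makeWorld(c(chrA = 6e6), spacing = 1e6, seed = 53)
  sim <- applyEdits(w$ref, editSpec("inversion", "chrA", 1250001, 2750000))
  asm <- sim$genome; names(asm) <- "s1"
  calls <- callOn(w, asm)
  expect_equal(length(calls[mcols(calls)$type == "inversion"]), 0L)
  # the same event is called once minMarkers = 1
  calls1 <- callOn(w, asm, minMarkers = 1)
  expect_equal(length(calls1[mcols(calls1)$type == "inversion"]), 1L)
})

test_that("guaranteed detectable length: brute force, closed form, printed anchors", {
  # the two marker geometries used genome-wide
  expect_equal(guaranteedDetectableLength(1e6, 2000, 2), 2001999)
  expect_equal(guaranteedDetectableLength(1e5, 2000, 2), 201999)
  # closed form k*s + m - 1 equals the brute force across a sweep
  for (s in c(1e4, 5e4, 2e5)) {
    for (m in c(1000, 2000)) {
      for (k in 1:3) {
        expect_equal(guaranteedDetectableLength(s, m, k),
                     guaranteedDetectableLength(s, m, k, bruteForce = FALSE))
      }
      # k = 1 specializes to s + m - 1
      expect_equal(guaranteedDetectableLength(s, m, 1), s + m - 1)
    }
  }
})

test_that("a translocated block is called on the foreign scaffold", {
  w <- makeWorld(c(chrA = 8e6, chrB = 8e6), spacing = 1e6, seed = 54)
  # move a segment containing 5 chrA markers (2,000,001..6,000,001) into chrB
  sim <- applyEdits(w$ref, editSpec("translocation", "chrA",
                                    1999001, 6999000,
                                    dest_chrom = "chrB", dest_pos = 7500000))
  asm <- sim$genome
  names(asm) <- c("sA", "sB")
  calls <- callOn(w, asm)
  trl <- calls[mcols(calls)$type == "translocation"]
  expect_equal(length(trl), 1L)
  expect_equal(mcols(trl)$n_markers, 5L)
  expect_identical(mcols(trl)$subject_id, "sB")
  expect_identical(as.character(seqnames(trl)), "chrA")
  expect_equal(start(trl), 2000001)

  # a single stray marker is below the threshold
  sim1 <- applyEdits(w$ref, editSpec("translocation", "chrA",
                                     1999001, 2999000,
                                     dest_chrom = "chrB", dest_pos = 7500000))
  asm1 <- sim1$genome; names(asm1) <- c("sA", "sB")
  calls1 <- callOn(w, asm1)
  expect_equal(length(calls1[mcols(calls1)$type == "translocation"]), 0L)
})

test_that("spanSupport counts flanked alignments with inclusive boundaries", {
  expect_equal(spanSupport(data.frame(start = 0, end = 50000), 25000), 1L)
  # ending exactly at breakpoint + flank is counted
  expect_equal(spanSupport(data.frame(start = 10000, end = 35000),
                           25000, flank = 10000), 1L)
  expect_equal(spanSupport(data.frame(start = 10000, end = 34999),
                           25000, flank = 10000), 0L)
  expect_error(spanSupport(data.frame(start = 1, end = 2), 1, flank = 0),
               "positive")
  # predicate oracle on 200 random intervals
  set.seed(8)
  al <- data.frame(start = sample.int(1e6, 200))
  al$end <- al$start + sample.int(1e5, 200)
  bp <- 5e5; fl <- 1e4
  oracle <- sum(vapply(seq_len(200), function(i)
    al$start[i] <= bp - fl && al$end[i] >= bp + fl, logical(1)))
  expect_equal(spanSupport(al, bp, fl), oracle)
})

test_that("genotype matrix merges shared loci by reciprocal overlap", {
  mk <- function(chrom, s, e, lab)
    GRanges(chrom, IRanges(s, e), type = "inversion", n_markers = 3L,
            subject_id = "s", assembly_label = lab)
  # one assembly, one call
  g1 <- genotypeMatrix(mk("chr1", 1e6 + 1, 3e6 + 1, "A"))
  expect_equal(dim(g1$matrix), c(1L, 1L))
  expect_true(g1$matrix[1, "A"])
  # identical call in two assemblies -> one locus, both present
  g2 <- genotypeMatrix(c(mk("chr1", 1e6 + 1, 3e6 + 1, "A"),
                         mk("chr1", 1e6 + 1, 3e6 + 1, "B")))
  expect_equal(nrow(g2$matrix), 1L)
  expect_true(all(g2$matrix[1, ]))
  # 50% overlap stays split at threshold 0.8
  g3 <- genotypeMatrix(c(mk("chr1", 1, 2e6, "A"),
                         mk("chr1", 1e6 + 1, 3e6, "B")))
  expect_equal(nrow(g3$matrix), 2L)
  # but merges at threshold 0.5
  g4 <- genotypeMatrix(c(mk("chr1", 1, 2e6, "A"),
                         mk("chr1", 1e6 + 1, 3e6, "B")),
                       reciprocalOverlap = 0.5)
  expect_equal(nrow(g4$matrix), 1L)
  # different chromosomes never merge
  g5 <- genotypeMatrix(suppressWarnings(
    c(mk("chr1", 1, 2e6, "A"), mk("chr2", 1, 2e6, "B"))))
  expect_equal(nrow(g5$matrix), 2L)
})
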