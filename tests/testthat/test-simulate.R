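# Synthetic genomes, planted edits with ground truth, scaffold gaps, reads.

test_that("randomGenome is seeded, sized and GC-calibrated", {
  g1 <- randomGenome(c(3e5, 2e5), seed = 10)
  g2 <- randomGenome(c(3e5, 2e5), seed = 10)
  expect_identical(as.character(g1), as.character(g2))
  expect_identical(names(g1), c("chr1", "chr2"))
  expect_equal(width(g1), c(3e5, 2e5))
  g3 <- randomGenome(c(3e5, 2e5), seed = 11)
  expect_false(identical(as.character(g1), as.character(g3)))
  # GC within 3 sigma of the binomial expectation at gc = 0.5
  g <- randomGenome(c(c1 = 1e6), gc = 0.5, seed = 12)
  gc_count <- sum(letterFrequency(g, c("G", "C"))[1, ])
  expect_lt(abs(gc_count - 5e5), 3 * sqrt(1e6 * 0.25))
})

test_that("inversion edits reverse-complement the segment in place", {
  g <- randomGenome(c(chrA = 5e4, chrB = 3e4), seed = 13)
  e <- editSpec("inversion", "chrA", 10001, 20000)
  sim <- applyEdits(g, e)
  expect_equal(width(sim$genome), width(g))
  # base-by-base revcomp oracle
  seg_new <- subseq(sim$genome[["chrA"]], 10001, 20000)
  seg_old <- subseq(g[["chrA"]], 10001, 20000)
  expect_identical(as.character(seg_new),
                   as.character(reverseComplement(seg_old)))
  # flanks untouched
  expect_identical(as.character(subseq(sim$genome[["chrA"]], 1, 10000)),
                   as.character(subseq(g[["chrA"]], 1, 10000)))
  # involution
  back <- applyEdits(sim$genome, e)$genome
  expect_identical(as.character(back), as.character(g))
})

test_that("deletions and translocations move exactly the stated bases", {
  g <- randomGenome(c(chrA = 5e4, chrB = 3e4), seed = 14)
  del <- applyEdits(g, editSpec("deletion", "chrA", 1001, 2000))$genome
  expect_equal(width(del)[1], 5e4 - 1000)
  expect_identical(as.character(subseq(del[["chrA"]], 1, 1000)),
                   as.character(subseq(g[["chrA"]], 1, 1000)))

  trl <- applyEdits(g, editSpec("translocation", "chrA", 1001, 3000,
                                dest_chrom = "chrB", dest_pos = 5001))$genome
  expect_equal(width(trl), c(5e4 - 2000, 3e4 + 2000))
  expect_identical(as.character(subseq(trl[["chrB"]], 5001, 7000)),
                   as.character(subseq(g[["chrA"]], 1001, 3000)))
  expect_identical(as.character(subseq(trl[["chrB"]], 1, 5000)),
                   as.character(subseq(g[["chrB"]], 1, 5000)))
})

test_that("invalid edit sets are rejected", {
  g <- randomGenome(c(chrA = 5e4), seed = 15)
  ov <- rbind(editSpec("inversion", "chrA", 1000, 5000),
              editSpec("deletion", "chrA", 4000, 6000))
  expect_error(applyEdits(g, ov), "overlap")
  expect_error(applyEdits(g, editSpec("inversion", "chrA", 100, 9e4)),
               "past the end")
  expect_error(editSpec("inversion", "chrA", 500, 100), "start")
  expect_error(editSpec("flip", "chrA", 1, 10), "unknown")
  expect_error(editSpec("translocation", "chrA", 1, 10), "dest")
})

test_that("scaffold joins contain runs of exactly gapLen N", {
  g <- randomGenome(c(chrA = 1e5), seed = 16)
  sc <- fragmentAndScaffold(g, list(chrA = 40000))
  expect_equal(width(sc)[1], 1e5 + 100)
  runs <- gregexpr("N+", as.character(sc[[1]]))[[1]]
  expect_equal(length(runs), 1L)
  expect_equal(attr(runs, "match.length"), 100L)
  # zero breaks: unchanged
  expect_identical(as.character(fragmentAndScaffold(g, list())),
                   as.character(g))
  # 3 breaks on a 1-Mb chromosome -> 1,000,300 bp
  g2 <- randomGenome(c(chrA = 1e6), seed = 17)
  sc2 <- fragmentAndScaffold(g2, list(chrA = c(2e5, 5e5, 8e5)))
  expect_equal(width(sc2)[1], 1000300L)
  # removing the gaps restores the original contigs in order
  expect_identical(gsub("N", "", as.character(sc2[[1]])),
                   as.character(g2[[1]]))
  expect_error(fragmentAndScaffold(g, list(chrA = 1e5)), "inside")
})

test_that("simulated reads honor the coverage stopping rule and are exact substrings", {
  g <- randomGenome(c(c1 = 1e5, c2 = 5e4), seed = 18)
  reads <- simulateReads(g, coverage = 4, readLenMean = 2000,
                         errorRate = 0, seed = 19)
  total <- sum(width(reads))
  expect_gte(total, 4 * 1.5e5)
  expect_lt(total, 4 * 1.5e5 + max(width(reads)))
  # strand-aware substring oracle via the encoded origin
  meta <- sub("^read[0-9]+ ", "", names(reads))
  for (i in sample(length(reads), 25)) {
    m <- regmatches(meta[i],
                    regexec("^(.+):([0-9]+)-([0-9]+)/([+-])$", meta[i]))[[1]]
    src <- subseq(g[[m[2]]], as.integer(m[3]), as.integer(m[4]))
    if (m[5] == "-") src <- reverseComplement(src)
    expect_identical(as.character(reads[[i]]), as.character(src))
  }
  # determinism: identical FASTQ bytes for a fixed seed
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  simulateReads(g, 2, readLenMean = 2000, seed = 20, output = f1)
  simulateReads(g, 2, readLenMean = 2000, seed = 20, output = f2)
  expect_identical(readLines(f1), readLines(f2))
  # substitution errors perturb reads at roughly the stated rate
  noisy <- simulateReads(g, 2, readLenMean = 2000, errorRate = 0.01,
                         seed = 21)
  meta1 <- sub("^read[0-9]+ ", "", names(noisy)[1])
  m <- regmatches(meta1, regexec("^(.+):([0-9]+)-([0-9]+)/([+-])$",
                                 meta1))[[1]]
  src <- subseq(g[[m[2]]], as.integer(m[3]), as.integer(m[4]))
  if (m[5] == "-") src <- reverseComplement(src)
  ed <- neditStartingAt(noisy[[1]], DNAString(as.character(src)),
                        starting.at = 1)
  expect_gt(ed, 0)
  expect_lt(ed, 0.05 * width(noisy)[1])
})

test_that("truth sets round trip through JSON", {
  edits <- rbind(editSpec("inversion", "chrA", 1e6 + 1, 3e6),
                 editSpec("translocation", "chrB", 1001, 5000,
                          dest_chrom = "chrC", dest_pos = 777))
  g <- randomGenome(c(chrA = 4e6, chrB = 1e4, chrC = 1e4), seed = 22)
  sim <- applyEdits(g, edits, seed = 22, substitutionRate = 0.001,
                    breaks = list(chrA = c(2e6)))
  tf <- withr::local_tempfile(fileext = ".json")
  writeTruth(sim$truth, tf)
  back <- readTruth(tf)
  expect_equal(back$edits$type, edits$type)
  expect_equal(back$edits$start, edits$start)
  expect_equal(back$edits$end, edits$end)
  expect_equal(back$edits$dest_pos, edits$dest_pos)
  expect_equal(back$substitution_rate, 0.001)
  expect_equal(back$breaks$chrA, 2e6)
})
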