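# Scaffold assignment, collinear-block segmentation, linearity metrics.

# Build a placements data.frame by hand (grid spacing 1e5, marker len 2000).
mkPlacements <- function(ref_start, subject_id, subject_start, strand,
                         chrom = "chrA") {
  data.frame(
    marker_id = paste0(chrom, "_", ref_start), ref_chrom = chrom,
    ref_start = as.integer(ref_start), subject_id = subject_id,
    subject_start = as.integer(subject_start), strand = strand,
    pident = 100, aln_len = 2000L, score = 100, ambiguous = FALSE,
    stringsAsFactors = FALSE)
}

test_that("identity assembly: self-assignment, one +1 block per chromosome, metrics 1.0", {
  w <- makeWorld(c(chrA = 5e5, chrB = 3e5), spacing = 1e5)
  res <- placeOn(w, w$ref)
  a <- res$assignments
  expect_identical(a$subject_id, a$chrom)
  expect_true(all(a$orientation == "+"))
  expect_true(all(a$is_primary))
  blocks <- segmentBlocks(res$placed, a, spacing = w$spacing)
  expect_equal(nrow(blocks), 2L)
  expect_true(all(blocks$sign == 1L))
  expect_equal(sum(blocks$n_markers), nrow(res$placed))
  m <- linearityMetrics(res$placed, a, w$markers)
  expect_true(all(m$marker_recovery == 1))
  expect_true(all(m$primary_recovery == 1))
  expect_true(all(m$collinearity == 1))
})

test_that("a reverse-complemented scaffold is assigned with minus orientation and normalizes away", {
  w <- makeWorld(c(chrA = 5e5, chrB = 3e5), spacing = 1e5)
  asm <- w$ref
  asm[["chrB"]] <- reverseComplement(asm[["chrB"]])
  names(asm) <- c("s1", "s2")
  res <- placeOn(w, asm)
  a <- res$assignments
  expect_identical(a$chrom[a$subject_id == "s2"], "chrB")
  expect_identical(a$orientation[a$subject_id == "s2"], "-")
  # segmentation invariant under whole-scaffold reverse complement
  blocks <- segmentBlocks(res$placed, a, spacing = w$spacing)
  expect_true(all(blocks$sign == 1L))
  expect_equal(nrow(blocks[blocks$chrom == "chrB", ]), 1L)
  m <- linearityMetrics(res$placed, a, w$markers)
  expect_true(all(m$collinearity == 1))
})

test_that("scaffold chromosome vote follows the majority, ties lexicographic", {
  p <- rbind(
    mkPlacements(seq(1, by = 1e5, length.out = 60), "scX",
                 seq(1, by = 1e5, length.out = 60), "+", chrom = "chrA"),
    mkPlacements(seq(1, by = 1e5, length.out = 40), "scX",
                 seq(6000001, by = 1e5, length.out = 40), "+", chrom = "chrB"))
  a <- assignScaffolds(p, c(scX = 1e7))
  expect_identical(a$chrom, "chrA")   # 60/100 majority
  expect_equal(a$n_support, 60L)
  # tie: equal counts -> lexicographically smaller chromosome, with a message
  p2 <- rbind(
    mkPlacements(c(1, 100001), "scY", c(1, 100001), "+", chrom = "chrB"),
    mkPlacements(c(1, 100001), "scY", c(200001, 300001), "+", chrom = "chrA"))
  expect_message(a2 <- assignScaffolds(p2, c(scY = 1e6)), "tie")
  expect_identical(a2$chrom, "chrA")
})

test_that("segmentation splits chains on strand flips and scaffold jumps", {
  s <- 1e5
  # markers 1-3 forward, 4-6 reversed order on minus strand, 7-10 forward
  ref <- seq(1, by = s, length.out = 10)
  sub <- c(1, 100001, 200001,          # diagonal
           800001, 700001, 600001,     # anti-diagonal
           600001 + ref[7:10] - ref[7] + 300000)
  strand <- c(rep("+", 3), rep("-", 3), rep("+", 4))
  p <- mkPlacements(ref, "sc1", sub, strand)
  a <- data.frame(subject_id = "sc1", chrom = "chrA", n_support = 10L,
                  orientation = "+", subject_length = 2e6, is_primary = TRUE,
                  stringsAsFactors = FALSE)
  blocks <- segmentBlocks(p, a, spacing = s)
  expect_equal(blocks$sign, c(1L, -1L, 1L))
  expect_equal(blocks$n_markers, c(3L, 3L, 4L))
  expect_equal(sum(blocks$n_markers), nrow(p))

  # one marker jumping to another scaffold mid-chain breaks the chain twice
  p2 <- mkPlacements(ref[1:7], c(rep("sc1", 3), "sc2", rep("sc1", 3)),
                     c(1, 100001, 200001, 1, 400001, 500001, 600001),
                     rep("+", 7))
  a2 <- rbind(a, data.frame(subject_id = "sc2", chrom = "chrA",
                            n_support = 1L, orientation = "+",
                            subject_length = 1e6, is_primary = FALSE,
                            stringsAsFactors = FALSE))
  b2 <- segmentBlocks(p2, a2, spacing = s)
  expect_equal(nrow(b2), 3L)
  expect_equal(b2$subject_id, c("sc1", "sc2", "sc1"))
})

test_that("large positional jumps beyond gap tolerance break blocks", {
  s <- 1e5
  ref <- seq(1, by = s, length.out = 6)
  # marker 4 jumps 10 grid steps on the scaffold
  sub <- c(1, 100001, 200001, 1300001, 1400001, 1500001)
  p <- mkPlacements(ref, "sc1", sub, rep("+", 6))
  a <- data.frame(subject_id = "sc1", chrom = "chrA", n_support = 6L,
                  orientation = "+", subject_length = 2e6, is_primary = TRUE,
                  stringsAsFactors = FALSE)
  expect_equal(nrow(segmentBlocks(p, a, spacing = s, gapTol = 3)), 2L)
  expect_equal(nrow(segmentBlocks(p, a, spacing = s, gapTol = 12)), 1L)
})

test_that("LIS collinearity matches an O(n^2) oracle on permuted chains", {
  for (seed in 1:10) {
    x <- VirtualMarkers:::.withSeed(seed, sample(100))
    expect_equal(VirtualMarkers:::.lisLength(x), lisOracle(x))
  }
  # with ties and repeats (strictness)
  x <- c(1, 3, 3, 2, 5, 5, 4)
  expect_equal(VirtualMarkers:::.lisLength(x), lisOracle(x))

  # collinearity of an inverted chain equals LIS oracle / placed markers
  s <- 1e5
  ref <- seq(1, by = s, length.out = 100)
  sub <- ref
  sub[30:50] <- rev(ref[30:50])  # a 2.1-Mb inversion at 100-kb spacing
  p <- mkPlacements(ref, "sc1", sub, c(rep("+", 29), rep("-", 21), rep("+", 50)))
  a <- data.frame(subject_id = "sc1", chrom = "chrA", n_support = 100L,
                  orientation = "+", subject_length = 2e7, is_primary = TRUE,
                  stringsAsFactors = FALSE)
  w <- makeWorld(c(chrA = 1e7), spacing = s, seed = 30)
  # restrict expected markers to the constructed 100 (use a matching world)
  ms <- generateMarkers(randomGenome(c(chrA = 1e7 - 2000 + 2000), seed = 1),
                        spacing = s, markerLen = 2000)
  m <- linearityMetrics(p, a, ms)
  expect_equal(m$collinearity, lisOracle(sub) / 100)
})

test_that("missing marker loci reduce recovery proportionally", {
  s <- 1e5
  ref <- seq(1, by = s, length.out = 100)
  keep <- setdiff(seq_len(100), c(10, 20, 30, 40, 50))
  p <- mkPlacements(ref[keep], "sc1", ref[keep], "+")
  a <- data.frame(subject_id = "sc1", chrom = "chrA", n_support = 95L,
                  orientation = "+", subject_length = 1e7 + 100,
                  is_primary = TRUE, stringsAsFactors = FALSE)
  ms <- generateMarkers(randomGenome(c(chrA = 1e7), seed = 2),
                        spacing = s, markerLen = 2000)
  m <- linearityMetrics(p, a, ms)
  expect_equal(m$marker_recovery, 0.95)
  expect_equal(m$primary_recovery, 0.95)
  expect_equal(m$collinearity, 1)
})
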