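test_that("distinct-peak counting reports every (peak, gene) pair once", {
  regions <- GRanges("chr1", IRanges(c(150, 180), c(400, 500)),
                     gene_id = c("g1", "g2"))
  peak <- GRanges("chr1", IRanges(100, 200))
  names(peak) <- "p1"
  res <- countOverlappingPeaks(peak, regions)
  expect_equal(observedOverlaps(res), 1L)           # one distinct peak
  expect_equal(nrow(overlapPairs(res)), 2L)         # but two pairs
  expect_equal(sort(overlapPairs(res)$gene_id), c("g1", "g2"))

  disjoint <- GRanges("chr1", IRanges(1000, 1100))
  expect_equal(observedOverlaps(countOverlappingPeaks(disjoint, regions)), 0L)
})

test_that("uniform-placement expectation matches the effective-target-size formula", {
  # 100 peaks of length 200, one 10 kb region, 1 Mb genome:
  # lambda = 100 * (10000 + 199) / 1e6 = 1.0199
  peaks <- GRanges("chr1", IRanges(rep(5000, 100), width = 200))
  region <- GRanges("chr1", IRanges(1001, 11000), gene_id = "g1")
  res <- poissonOverlapTest(peaks, region, c(chr1 = 1e6))
  expect_equal(expectedOverlaps(res), 1.0199, tolerance = 1e-12)
  # all 100 peaks were placed inside the region -> extreme upper tail
  expect_equal(observedOverlaps(res), 100L)
  expect_lt(overlapPValue(res), 1e-100)

  # observed = 0 gives p = 1 whatever lambda
  away <- GRanges("chr1", IRanges(rep(900000, 10), width = 200))
  expect_equal(overlapPValue(poissonOverlapTest(away, region, c(chr1 = 1e6))), 1)

  # unknown chromosome is an error
  bad <- GRanges("chr2", IRanges(1, 100))
  expect_error(poissonOverlapTest(bad, region, c(chr1 = 1e6)), "chr2")
})

test_that("the exact tail is monotone decreasing in the observed count", {
  probs <- runif(30, 0, 0.3)
  tails <- vapply(0:30, function(k) termloop:::.poisbinomTail(probs, k),
                  numeric(1))
  expect_equal(tails[1], 1)
  expect_true(all(diff(tails) < 0))
  # and agrees with the Poisson tail when probabilities are tiny
  small <- rep(1e-4, 50)
  expect_equal(termloop:::.poisbinomTail(small, 3),
               ppois(2, sum(small), lower.tail = FALSE), tolerance = 1e-4)
})

test_that("promoter/transcript peak filtering is idempotent and only removes overlaps", {
  g <- toyGenes()
  p <- toyPeaks()
  excl <- list(promoterRegions(g), granges(g))
  kept <- filterPeaks(p, excl)
  expect_setequal(names(kept),
                  c("p1", "p4", "p6", "p7", "p8", "p9", "p10", "p11", "p12"))
  expect_identical(names(filterPeaks(kept, excl)), names(kept))  # idempotent
  expect_identical(filterPeaks(p, list()), p)                    # identity
})

test_that("chromosome-aware shuffling is deterministic, saturates and calibrates", {
  g <- toyGenes()
  p <- toyPeaks()
  si <- toySeqinfo()
  tr <- terminationRegions(g)

  whole <- GRanges("chr1", IRanges(1, 100000), gene_id = "all")
  sat <- shuffleEnrichment(p, whole, si, nShuffles = 49, seed = 2)
  expect_equal(sat@observedFraction, 1)
  expect_equal(foldEnrichment(sat), 1)
  expect_equal(empiricalP(sat), 1)

  s1 <- shuffleEnrichment(p, tr, si, nShuffles = 99, seed = 42)
  s2 <- shuffleEnrichment(p, tr, si, nShuffles = 99, seed = 42)
  expect_identical(nullFractions(s1), nullFractions(s2))
  expect_identical(empiricalP(s1), empiricalP(s2))
  expect_gte(empiricalP(s1), 1 / 100)

  tooLong <- GRanges("chr1", IRanges(1, 200000))
  expect_error(shuffleEnrichment(tooLong, tr, si, nShuffles = 9),
               "longer than its chromosome")
})

test_that("planted TR peaks are recovered as fold enrichment with small empirical p", {
  cfg <- simulationConfig(seed = 19, nGenes = 50L, nPeaks = 100L,
                          chromLength = 2e6, fracPeaksInTR = 0.5)
  sim <- simulateGenome(cfg)
  pk <- simulatePeaks(cfg, sim$genes)
  tr <- suppressWarnings(terminationRegions(sim$genes, genome = sim$seqinfo))
  sh <- shuffleEnrichment(pk$peaks, tr, sim$seqinfo, nShuffles = 999, seed = 5)
  expect_gt(foldEnrichment(sh), 1)
  expect_lte(empiricalP(sh), 0.01)
})

test_that("the TR gene table separates peak-level and gene-level counts", {
  g <- toyGenes()
  p <- toyPeaks()
  kept <- filterPeaks(p, list(promoterRegions(g), granges(g)))
  tab <- trGeneTable(kept, g, expression = toyExpression())
  # hand enumeration: p1-g1 p4-g2 p6-g3 p7-g3 p8-g4 p9-g5 p12-g3
  expect_equal(nrow(tab), 7L)
  expect_equal(metadata(tab)$nPeaks, 7L)
  expect_equal(metadata(tab)$nGenes, 5L)
  expect_equal(sum(tab$gene_id == "g3"), 3L)
  expect_setequal(tab$gene_id[tab$expressed], c("g1", "g3", "g3", "g3", "g5"))

  empty <- trGeneTable(kept[0], g)
  expect_equal(nrow(empty), 0L)
  expect_equal(metadata(empty)$nPeaks, 0L)
  expect_equal(metadata(empty)$nGenes, 0L)
})
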