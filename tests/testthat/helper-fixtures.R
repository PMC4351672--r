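suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# Hand-constructed 5-gene / 12-peak world on one 100 kb chromosome.
# All coordinates 1-based closed. Derived region coordinates (defaults):
#   TRs:       g1 [20001,24000] g2 [26001,30000] g3 [56001,60000]
#              g4 [70001,74000] g5 [84001,88000]
#   promoters: g1 [8751,10000]  g2 [40001,41250] g3 [48751,50000]
#              g4 [63751,65000] g5 [78751,80000]
toySeqinfo <- function() Seqinfo("chr1", 100000L)

toyGenes <- function() {
  g <- GRanges("chr1",
               IRanges(start = c(10001, 30001, 50001, 65001, 80001),
                       end   = c(20000, 40000, 56000, 70000, 84000)),
               strand = c("+", "-", "+", "+", "+"),
               gene_id = paste0("g", 1:5),
               seqinfo = toySeqinfo())
  names(g) <- g$gene_id
  g
}

# Peak placement relative to the regions above:
#   p1 TR(g1) only; p2 TR(g1)+transcript(g1); p3 promoter(g1) only;
#   p4 TR(g2) only; p5 TR(g2)+transcript(g2); p6,p7 TR(g3);
#   p8 TR(g4) only; p9 TR(g5) only; p10,p11 background; p12 TR(g3) edge.
toyPeaks <- function() {
  p <- GRanges("chr1",
               IRanges(start = c(20101, 19900,  9000, 27001, 29950, 56101,
                                 57000, 73900, 84101, 45000, 95000, 59900),
                       end   = c(20300, 20100,  9500, 27200, 30050, 56200,
                                 57400, 74100, 84200, 45100, 95500, 60100)),
               name = sprintf("p%d", 1:12),
               seqinfo = toySeqinfo())
  names(p) <- p$name
  p
}

# Expression: expressed (>= 1) are g1, g3, g5.
toyExpression <- function() {
  c(g1 = 5, g2 = 0.5, g3 = 2, g4 = 0, g5 = 10)
}

# Independent uniform-placement null for the overlap test: peak starts drawn
# uniformly on [1, G] (extent clipped at G), overlap checked by plain
# interval arithmetic, add-one empirical p. Deliberately avoids the
# package's overlap machinery.
uniformPlacementP <- function(peakLens, regStarts, regEnds, G, observed,
                              nDraws = 1e5, seed = 1, chunk = 20000L) {
  withr::with_seed(seed, {
    exceed <- 0L
    done <- 0L
    n <- length(peakLens)
    while (done < nDraws) {
      m <- min(chunk, nDraws - done)
      S <- matrix(floor(runif(m * n) * G) + 1, nrow = m)
      E <- S + matrix(peakLens, nrow = m, ncol = n, byrow = TRUE) - 1
      E[E > G] <- G
      hit <- matrix(FALSE, m, n)
      for (i in seq_along(regStarts))
        hit <- hit | (S <= regEnds[i] & E >= regStarts[i])
      exceed <- exceed + sum(rowSums(hit) >= observed)
      done <- done + m
    }
  })
  (1 + exceed) / (nDraws + 1)
}

# Random binary hit matrix (genes x patients) for CMH property tests.
randomHits <- function(nGenes, cohort, p = 0.3) {
  matrix(rbinom(nGenes * length(cohort), 1, p), nrow = nGenes,
         dimnames = list(sprintf("g%03d", seq_len(nGenes)), names(cohort)))
}

toyCohort <- function(nA = 2, nB = 2, groupA = "BRCA1", groupB = "sporadic") {
  setNames(rep(c(groupA, groupB), c(nA, nB)),
           c(sprintf("a%d", seq_len(nA)), sprintf("b%d", seq_len(nB))))
}
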