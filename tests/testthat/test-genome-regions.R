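test_that("GTF and BED gene models parse with correct coordinates and TSS/TTS", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id "gA";',
    'chr1\tsrc\tgene\t5001\t9000\t.\t-\t.\tgene_id "gB";'), gtf)
  g <- readGeneModels(gtf)
  expect_equal(length(g), 2L)
  expect_equal(start(g["gA"]), 1001L)
  expect_equal(end(g["gA"]), 2000L)
  expect_equal(unname(geneTSS(g)["gA"]), 1001)
  expect_equal(unname(geneTTS(g)["gA"]), 2000)
  # minus strand: TSS is the higher coordinate
  expect_equal(unname(geneTSS(g)["gB"]), 9000)
  expect_equal(unname(geneTTS(g)["gB"]), 5001)

  # BED line "chr1 999 2000 g1 0 -" (0-based half-open) -> 1-based 1000..2000
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tg1\t0\t-", bed)
  b <- readGeneModels(bed)
  expect_equal(start(b), 1000L)
  expect_equal(end(b), 2000L)
  expect_equal(unname(geneTSS(b)), 2000)
  expect_equal(unname(geneTTS(b)), 1000)
})

test_that("multi-transcript genes collapse to the most extreme 3' end and unknown strands are skipped", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t1001\t2000\t.\t+\t.\tgene_id "gA"; transcript_id "t1";',
    'chr1\tsrc\ttranscript\t1001\t3000\t.\t+\t.\tgene_id "gA"; transcript_id "t2";',
    'chr1\tsrc\ttranscript\t5001\t6000\t.\t.\t.\tgene_id "gC"; transcript_id "t3";'),
    gtf)
  expect_warning(g <- readGeneModels(gtf), "unknown strand")
  expect_equal(g$gene_id, "gA")
  expect_equal(end(g), 3000L)
})

test_that("gene models round-trip through BED identically", {
  sim <- simulateGenome(simulationConfig(seed = 11, nGenes = 3L,
                                         chromLength = 2e5))
  dir <- tempfile(); dir.create(dir)
  gtfPath <- file.path(dir, "genes.gtf")
  gtf <- granges(sim$genes)
  gtf$source <- "sim"; gtf$type <- "gene"; gtf$gene_id <- sim$genes$gene_id
  rtracklayer::export(gtf, gtfPath, format = "gtf")
  g1 <- readGeneModels(gtfPath)
  bedPath <- file.path(dir, "genes.bed")
  exportRegions(g1, bedPath)
  g2 <- readGeneModels(bedPath)
  expect_equal(start(g1), start(g2))
  expect_equal(end(g1), end(g2))
  expect_equal(as.character(strand(g1)), as.character(strand(g2)))
  expect_equal(g1$gene_id, g2$gene_id)
})

test_that("termination regions extend 4 kb downstream of the TTS, strand-aware", {
  g <- toyGenes()
  tr <- terminationRegions(g)
  # + strand gene ending at 20000 -> [20001, 24000]
  expect_equal(start(tr["g1"]), 20001L)
  expect_equal(end(tr["g1"]), 24000L)
  # - strand gene starting at 30001 -> [26001, 30000]
  expect_equal(start(tr["g2"]), 26001L)
  expect_equal(end(tr["g2"]), 30000L)
  expect_true(all(width(tr) == 4000))
  expect_equal(names(tr), g$gene_id)
})

test_that("TRs are clipped at chromosome ends, preserving the gene count", {
  g <- GRanges("chr1", IRanges(90001, 99000), strand = "+", gene_id = "gE",
               seqinfo = Seqinfo("chr1", 100000L))
  expect_warning(tr <- terminationRegions(g), "clipped")
  expect_equal(start(tr), 99001L)
  expect_equal(end(tr), 100000L)
  expect_equal(length(tr), 1L)
})

test_that("whole-gene regions span TSS-1250 to TTS+5000 in transcription direction", {
  g <- toyGenes()
  wg <- wholeGeneRegions(g)
  # g1: + strand [10001, 20000] -> [8751, 25000]
  expect_equal(start(wg["g1"]), 8751L)
  expect_equal(end(wg["g1"]), 25000L)
  # g2: - strand [30001, 40000] -> [25001, 41250]
  expect_equal(start(wg["g2"]), 25001L)
  expect_equal(end(wg["g2"]), 41250L)
  # identity case
  wg0 <- wholeGeneRegions(g, upstream = 0, downstream = 0)
  expect_equal(ranges(wg0), ranges(granges(g)))
  # containment: TR within whole-gene region when downstream >= TR length
  tr <- terminationRegions(g)
  expect_true(all(start(wg) <= start(tr) & end(tr) <= end(wg)))
})

test_that("TTS windows are symmetric about the TTS and reject empty flanks", {
  g <- toyGenes()
  w <- ttsWindows(g)
  # g1 TTS boundary at 20000|20001 -> [16001, 24000]
  expect_equal(start(w["g1"]), 16001L)
  expect_equal(end(w["g1"]), 24000L)
  # g2 (- strand, TTS at 30001) -> [26001, 34000]
  expect_equal(start(w["g2"]), 26001L)
  expect_equal(end(w["g2"]), 34000L)
  expect_true(all(width(w) == 8000))
  expect_error(ttsWindows(g, flank = 0), "empty")
  # left clip
  gl <- GRanges("chr1", IRanges(1001, 3000), strand = "+", gene_id = "gL",
                seqinfo = toySeqinfo())
  expect_warning(wl <- ttsWindows(gl), "clipped")
  expect_equal(start(wl), 1L)
  expect_equal(end(wl), 7000L)
})

test_that("promoters cover the 1250 bp upstream of the TSS, strand-aware", {
  g <- toyGenes()
  pr <- promoterRegions(g)
  expect_equal(start(pr["g1"]), 8751L)   # + strand, TSS 10001
  expect_equal(end(pr["g1"]), 10000L)
  expect_equal(start(pr["g2"]), 40001L)  # - strand, TSS 40000
  expect_equal(end(pr["g2"]), 41250L)
  expect_error(promoterRegions(g, upstream = 0, downstream = 0), "empty")
})

test_that("region construction commutes with mirroring the genome", {
  L <- 100000L
  g <- toyGenes()
  mirror <- function(gr) {
    out <- GRanges(seqnames(gr),
                   IRanges(L - end(gr) + 1L, L - start(gr) + 1L),
                   strand = ifelse(strand(gr) == "+", "-", "+"),
                   gene_id = gr$gene_id, seqinfo = seqinfo(gr))
    names(out) <- gr$gene_id
    out
  }
  for (build in list(terminationRegions, wholeGeneRegions, ttsWindows,
                     promoterRegions)) {
    a <- mirror(build(mirror(g)))
    b <- build(g)
    expect_equal(ranges(a), ranges(b))
  }
})

test_that("region sets round-trip through BED", {
  g <- toyGenes()
  tr <- terminationRegions(g)
  bed <- tempfile(fileext = ".bed")
  exportRegions(tr, bed)
  back <- rtracklayer::import(bed, format = "bed")
  expect_equal(start(back), start(tr))
  expect_equal(end(back), end(tr))
  expect_equal(back$name, names(tr))
})
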