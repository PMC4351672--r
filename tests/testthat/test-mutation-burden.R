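test_that("VCF records classify into substitutions and indels", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    "chr1\t500\t.\tA\tT\t.\tPASS\t.",
    "chr1\t700\t.\tAT\tA\t.\tPASS\t.",
    "chr1\t900\t.\tG\tGCC\t.\tPASS\t."), vcf)
  rec <- readMutationCatalog(vcf, patient = "pt1")
  expect_equal(as.character(rec$mclass), c("SBM", "indel", "indel"))
  expect_equal(start(rec), c(500L, 700L, 900L))
  expect_true(all(rec$patient_id == "pt1"))
  expect_error(readMutationCatalog(vcf), "patient")
})

test_that("mutation TSVs round-trip and unknown classes name their line", {
  pos <- withr::with_seed(5, sample(1:90000, 10))
  rec <- GRanges("chr1", IRanges(pos, width = 1),
                 patient_id = rep(c("p1", "p2"), 5),
                 mclass = rep(c("SBM", "indel", "rearrangement", "SBM",
                                "indel"), 2),
                 ref = NA_character_, alt = NA_character_)
  f <- tempfile(fileext = ".tsv")
  writeMutationCatalog(sort(rec), f)
  back <- readMutationCatalog(f)
  expect_equal(length(back), 10L)
  expect_equal(start(back), start(sort(rec)))
  expect_equal(as.character(back$mclass), as.character(sort(rec)$mclass))

  bad <- readLines(f)
  bad[3] <- sub("\t(SBM|indel|rearrangement)", "\tsplice", bad[3])
  writeLines(bad, f)
  expect_error(readMutationCatalog(f), "line 3")
})

test_that("germline subtraction removes same-patient same-class matches only", {
  tumor <- GRanges("chr1", IRanges(c(100, 200, 300, 400, 500, 600, 700, 800,
                                     900, 1000), width = 1),
                   patient_id = "p1",
                   mclass = rep(c("SBM", "indel"), 5))
  normal <- GRanges("chr1", IRanges(c(100, 300, 500), width = 1),
                    patient_id = "p1", mclass = c("SBM", "indel", "SBM"))
  kept <- subtractGermline(tumor, normal)
  # 100 and 500 are SBM in both and go; 300 is SBM in tumor, indel in normal
  expect_equal(length(kept), 8L)
  expect_false(any(start(kept) %in% c(100, 500)))
  expect_true(300 %in% start(kept))
  # idempotent, and identity on an empty normal set
  expect_equal(length(subtractGermline(kept, normal)), 8L)
  expect_identical(subtractGermline(tumor, tumor[0]), tumor)
  # other patients are untouched
  normal2 <- normal
  normal2$patient_id <- "p2"
  expect_identical(subtractGermline(tumor, normal2), tumor)
})

test_that("regional hits honour the inclusive region end and binarization", {
  regions <- GRanges("chr1", IRanges(1001, 2000), gene_id = "g1")
  cohort <- c(p1 = "BRCA1", p2 = "sporadic")
  mk <- function(pos, pat = "p1") GRanges("chr1", IRanges(pos, width = 1),
                                          patient_id = pat, mclass = "indel")
  expect_equal(countRegionHits(mk(2000), regions, cohort, "indel")["g1", "p1"],
               1L)  # last base of region
  expect_equal(countRegionHits(mk(2001), regions, cohort, "indel")["g1", "p1"],
               0L)  # first base past the region
  # three indels in one region binarize to a single hit
  three <- mk(c(1100, 1200, 1300))
  expect_equal(countRegionHits(three, regions, cohort, "indel")["g1", "p1"], 1L)
  expect_equal(countRegionHits(three, regions, cohort, "indel",
                               binarize = FALSE)["g1", "p1"], 3L)
})

test_that("the hit table matches hand enumeration on a 4-patient, 3-gene fixture", {
  regions <- GRanges("chr1", IRanges(c(1001, 5001, 9001), width = 1000),
                     gene_id = c("g1", "g2", "g3"))
  cohort <- c(p1 = "BRCA1", p2 = "BRCA1", p3 = "sporadic", p4 = "sporadic")
  rec <- GRanges("chr1",
                 IRanges(c(1100, 1200, 5500, 9100,   5600,   1500,  400),
                         width = 1),
                 patient_id = c("p1", "p1", "p1", "p2", "p3", "p4", "p4"),
                 mclass = "SBM")
  hits <- countRegionHits(rec, regions, cohort, "SBM")
  want <- matrix(c(1L, 0L, 0L, 1L,   # g1: p1 (twice, binarized), p4
                   1L, 0L, 1L, 0L,   # g2: p1, p3
                   0L, 1L, 0L, 0L),  # g3: p2
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), names(cohort)))
  expect_identical(hits, want)
})

test_that("the CMH Z statistic matches direct evaluation and its symmetries", {
  # single stratum, one patient per group, only the group-A patient hit:
  # a = 1, E = 0.5, V = 0.25 -> Z = 1
  hits <- matrix(c(1L, 0L), nrow = 1, dimnames = list("g1", c("a1", "b1")))
  res <- cmhZ(hits, c(a1 = "BRCA1", b1 = "sporadic"), "BRCA1", "sporadic")
  expect_equal(cmhStatistic(res), 1.0)
  expect_equal(cmhPValue(res), pnorm(1, lower.tail = FALSE))

  # identical group rates with equal group sizes -> Z = 0
  cohort <- toyCohort(nA = 3, nB = 3)
  sym <- matrix(rep(c(1L, 1L, 0L, 1L, 1L, 0L), 4), nrow = 4, byrow = TRUE,
                dimnames = list(paste0("g", 1:4), names(cohort)))
  expect_equal(cmhStatistic(cmhZ(sym, cohort, "BRCA1", "sporadic")), 0)

  # count variant: one stratum with counts 3 vs 1, one patient per group:
  # T = 4, E = 2, V = 4 * 0.25 = 1 -> Z = 1
  cnt <- matrix(c(3L, 1L), nrow = 1, dimnames = list("g1", c("a1", "b1")))
  resC <- cmhZ(cnt, c(a1 = "BRCA1", b1 = "sporadic"), "BRCA1", "sporadic",
               variant = "count")
  expect_equal(cmhStatistic(resC), 1.0)

  # degenerate: no informative strata
  zero <- matrix(0L, nrow = 2, ncol = 6,
                 dimnames = list(c("g1", "g2"), names(cohort)))
  deg <- cmhZ(zero, cohort, "BRCA1", "sporadic")
  expect_true(deg@degenerate)
  expect_equal(cmhPValue(deg), 1)
})

test_that("a planted indel rate ratio is recovered by the panel at reduced scale", {
  cfg <- simulationConfig(seed = 31, nGenes = 120L, chromLength = 6e6,
                          theta = list(BRCA1 = list(indel = 4)))
  sim <- simulateGenome(cfg)
  trGenes <- sim$genes$gene_id[1:100]
  mut <- simulateMutations(cfg, sim$genes, trGenes)
  panel <- effectSizePanel(mut$mutations, sim$genes, mut$cohort, trGenes,
                           negGenes = setdiff(sim$genes$gene_id, trGenes),
                           regionTypes = "tts_window",
                           genome = sim$seqinfo)
  planted <- panel$z[panel$mclass == "indel" & panel$gene_set == "TR" &
                     panel$comparison == "BRCA1_vs_sporadic"]
  expect_gt(planted, 2)
  expect_equal(max(panel$z, na.rm = TRUE), planted)

  # empty catalog: every cell degenerate
  emptyPanel <- effectSizePanel(mut$mutations[0], sim$genes, mut$cohort,
                                trGenes, regionTypes = "tts_window",
                                genome = sim$seqinfo)
  expect_true(all(emptyPanel$degenerate))
  expect_true(all(emptyPanel$p == 1))
})

test_that("indel-to-peak distances use edge distance with inside = 0", {
  peaks <- GRanges("chr1", IRanges(9001, 10000), name = "pk1")
  at <- function(pos, chrom = "chr1") GRanges(chrom, IRanges(pos, width = 1),
                                              patient_id = "p1",
                                              mclass = "indel")
  expect_equal(distanceToNearestPeak(at(10351), peaks), 350)
  expect_equal(distanceToNearestPeak(at(9500), peaks), 0)
  expect_equal(distanceToNearestPeak(at(8800), peaks), 200)
  expect_warning(d <- distanceToNearestPeak(at(100, "chr9"), peaks),
                 "without peaks")
  expect_true(is.na(d))
})
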