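#' Count distinct peaks overlapping a region set
#'
#' A peak overlapping k regions counts once toward the observed total; every
#' (peak, gene) pair is reported so peak-level and gene-level tallies can be
#' separated. All overlap logic is strand-blind.
#'
#' @param peaks `GRanges` of peaks (names used as peak identifiers).
#' @param regions `GRanges` of regions with a `gene_id` column.
#' @param minOverlap minimum overlap in bp to count (default 1, any base).
#' @return an [OverlapResult-class] with `lambda`/`pValue` unset.
#' @export
countOverlappingPeaks <- function(peaks, regions, minOverlap = 1) {
  hits <- findOverlaps(peaks, regions, minoverlap = minOverlap,
                       ignore.strand = TRUE)
  peakNames <- if (!is.null(names(peaks))) names(peaks)
               else sprintf("peak_%d", seq_along(peaks))
  geneIds <- if (!is.null(regions$gene_id)) regions$gene_id
             else if (!is.null(names(regions))) names(regions)
             else sprintf("region_%d", seq_along(regions))
  pairs <- S4Vectors::DataFrame(peak = peakNames[queryHits(hits)],
                                gene_id = geneIds[subjectHits(hits)])
  new("OverlapResult",
      observed = length(unique(queryHits(hits))),
      nPeaks = length(peaks),
      lambda = NA_real_, pValue = NA_real_, method = "none",
      pairs = pairs)
}

# Per-peak probability of hitting >= 1 region when the peak start is drawn
# uniformly on [1, chrom length] (extent clipped at the chromosome end).
# A peak of length L with start s hits region [a, b] iff s is in
# [a - L + 1, b]; the probability is the width of the union of those
# windows over the chromosome length.
.peakHitProbs <- function(peaks, regions, si) {
  probs <- numeric(length(peaks))
  chroms <- as.character(seqnames(peaks))
  for (ch in unique(chroms)) {
    G <- seqlengths(si)[[ch]]
    if (is.na(G) || G <= 0) stop("missing or zero length for chromosome ", ch)
    idx <- which(chroms == ch)
    reg <- regions[seqnames(regions) == ch]
    if (!length(reg)) next
    for (L in unique(width(peaks)[idx])) {
      win <- IRanges::reduce(IRanges(pmax(1L, start(reg) - L + 1L), end(reg)))
      win <- restrict(win, 1L, as.integer(G))
      probs[idx[width(peaks)[idx] == L]] <- sum(width(win)) / G
    }
  }
  probs
}

#' Test peak-region overlap enrichment against a uniform-placement null
#'
#' Under the null each peak keeps its length and chromosome and its start is
#' uniform over the chromosome. The expected number of peaks overlapping at
#' least one region is `lambda = sum_j p_j`, where `p_j` is the per-peak hit
#' probability (the classical effective-target-size expectation
#' `n * sum_i(len_i + meanPeakLen - 1) / G` when the dilated regions are
#' disjoint). The upper tail `P(X >= observed)` is computed exactly from the
#' Poisson-binomial distribution of independent placements by default;
#' `method = "poisson"` gives the classical Poisson tail at `lambda`
#' instead, a good approximation when per-peak hit probabilities are small.
#'
#' @inheritParams countOverlappingPeaks
#' @param genome Seqinfo, named chromosome-length vector, or chrom.sizes
#'   path; must cover every peak chromosome.
#' @param method tail computation, "exact" (default) or "poisson".
#' @return an [OverlapResult-class] with `lambda` and `pValue` filled in.
#' @seealso [shuffleEnrichment()] for the permutation analogue.
#' @export
poissonOverlapTest <- function(peaks, regions, genome, minOverlap = 1,
                               method = c("exact", "poisson")) {
  method <- match.arg(method)
  si <- .asSeqinfo(genome)
  if (sum(as.numeric(seqlengths(si))) <= 0) stop("genome has zero total length")
  .checkChromsCovered(peaks, si, "peaks")
  res <- countOverlappingPeaks(peaks, regions, minOverlap = minOverlap)
  probs <- .peakHitProbs(peaks, regions, si)
  lambda <- sum(probs)
  p <- if (method == "poisson") {
    max(ppois(res@observed - 1L, lambda, lower.tail = FALSE), 1e-300)
  } else {
    .poisbinomTail(probs, res@observed)
  }
  initialize(res, lambda = lambda, pValue = p, method = method)
}

#' Remove peaks overlapping any exclusion region set
#'
#' Retains only peaks with zero overlap with every supplied exclusion set
#' (e.g. promoters and transcript spans). Idempotent; an empty exclusion
#' list returns the input unchanged.
#'
#' @param peaks `GRanges` of peaks.
#' @param exclusions a `GRanges`, `GRangesList` or list of `GRanges`.
#' @return the retained subset of `peaks`.
#' @export
filterPeaks <- function(peaks, exclusions) {
  if (is(exclusions, "GRanges")) exclusions <- list(exclusions)
  for (excl in as.list(exclusions))
    peaks <- subsetByOverlaps(peaks, excl, invert = TRUE, ignore.strand = TRUE)
  peaks
}

#' Chromosome-aware shuffle null for peak-region overlap
#'
#' Each shuffle relocates every peak uniformly at random within its own
#' chromosome (length preserved, extent clipped at the chromosome end) and
#' records the fraction of peaks overlapping at least one region. The
#' empirical p value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (nShuffles + 1)` and is therefore never
#' zero. Results are deterministic for a fixed seed; the caller's RNG state
#' is left untouched.
#'
#' @inheritParams poissonOverlapTest
#' @param nShuffles number of shuffles (>= 1).
#' @param seed integer RNG seed, recorded in the result.
#' @return a [ShuffleResult-class].
#' @export
shuffleEnrichment <- function(peaks, regions, genome, nShuffles = 1000,
                              seed = 1) {
  if (nShuffles < 1) stop("'nShuffles' must be >= 1")
  si <- .asSeqinfo(genome)
  .checkChromsCovered(peaks, si, "peaks")
  lens <- seqlengths(si)[as.character(seqnames(peaks))]
  if (any(width(peaks) > lens))
    stop("peak longer than its chromosome; cannot shuffle")
  observed <- countOverlappingPeaks(peaks, regions)@observed
  n <- length(peaks)
  nullFrac <- withr::with_seed(as.integer(seed), {
    starts <- matrix(
      floor(runif(n * nShuffles, min = 0, max = rep(lens, nShuffles))) + 1,
      nrow = n)
    ends <- pmin(starts + width(peaks) - 1L, lens)
    vapply(seq_len(nShuffles), function(k) {
      shuf <- GRanges(seqnames(peaks), IRanges(starts[, k], ends[, k]))
      length(unique(queryHits(
        findOverlaps(shuf, regions, ignore.strand = TRUE)))) / n
    }, numeric(1))
  })
  obsFrac <- observed / n
  new("ShuffleResult",
      observedFraction = obsFrac,
      nullFractions = nullFrac,
      empiricalP = (1 + sum(nullFrac >= obsFrac)) / (nShuffles + 1),
      foldEnrichment = if (mean(nullFrac) > 0) obsFrac / mean(nullFrac)
                       else NA_real_,
      nShuffles = as.integer(nShuffles), seed = as.integer(seed))
}

#' Tabulate TR-bound genes from retained peaks
#'
#' One row per (peak, gene) pair whose TR is overlapped by a retained peak,
#' with an `expressed` flag when an expression table is supplied. Peak-level
#' and gene-level tallies are recorded in `metadata()` since several peaks
#' may hit one gene's TR and one peak may hit several.
#'
#' @param peaks retained (filtered) peak `GRanges`.
#' @param genes stranded gene models.
#' @param trLength TR length in bp passed to [terminationRegions()].
#' @param expression optional named numeric expression vector.
#' @param threshold expression threshold defining "expressed" genes.
#' @param genome optional genome for TR clipping.
#' @return a `DataFrame` with columns `gene_id`, `peak`, `tr_start`,
#'   `tr_end`, and `expressed` (if expression given); metadata fields
#'   `nPeaks` and `nGenes` hold the deduplicated counts.
#' @export
trGeneTable <- function(peaks, genes, trLength = 4000, expression = NULL,
                        threshold = 1, genome = NULL) {
  trs <- terminationRegions(genes, length = trLength, genome = genome)
  hits <- findOverlaps(peaks, trs, ignore.strand = TRUE)
  peakNames <- if (!is.null(names(peaks))) names(peaks)
               else sprintf("peak_%d", seq_along(peaks))
  tab <- S4Vectors::DataFrame(
    gene_id = trs$gene_id[subjectHits(hits)],
    peak = peakNames[queryHits(hits)],
    tr_start = start(trs)[subjectHits(hits)],
    tr_end = end(trs)[subjectHits(hits)])
  if (!is.null(expression)) {
    expressed <- classifyExpressed(expression, threshold)
    tab$expressed <- tab$gene_id %in% expressed
  }
  S4Vectors::metadata(tab) <- list(
    nPeaks = length(unique(tab$peak)),
    nGenes = length(unique(tab$gene_id)))
  tab
}
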