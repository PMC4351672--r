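#' Total signal carried by a coverage track
#'
#' Sum over the genome of per-base value times interval width; used as a
#' library-size proxy when read counts are unavailable.
#'
#' @param track `GRanges` with a numeric `score` (bedGraph semantics:
#'   `score` is the per-base value over the interval).
#' @return a single number.
#' @export
totalSignal <- function(track) {
  sum(as.numeric(track$score) * width(track))
}

#' Quantify coverage over regions as RPKM
#'
#' For each region, the signal is the sum over overlapping track intervals
#' of per-base value times overlap width, scaled as
#' `RPKM = signal / (region kb) / (library millions)`:
#' reads (signal) per kilobase of region per million units of library.
#'
#' @param track coverage `GRanges` with `score` (see [readBedGraph()]).
#' @param regions `GRanges` of regions (names/`gene_id` label the result).
#' @param librarySize positive library size; defaults to
#'   [totalSignal()] of the track.
#' @return named numeric vector of per-region RPKM.
#' @export
rpkmOverRegions <- function(track, regions, librarySize = NULL) {
  if (any(width(regions) == 0L)) stop("zero-length region")
  if (is.null(librarySize)) librarySize <- totalSignal(track)
  if (!is.numeric(librarySize) || librarySize <= 0)
    stop("'librarySize' must be > 0")
  sig <- numeric(length(regions))
  hits <- findOverlaps(track, regions, ignore.strand = TRUE)
  if (length(hits)) {
    ov <- pintersect(ranges(track)[queryHits(hits)],
                     ranges(regions)[subjectHits(hits)])
    contrib <- track$score[queryHits(hits)] * width(ov)
    agg <- tapply(contrib, subjectHits(hits), sum)
    sig[as.integer(names(agg))] <- agg
  }
  rpkm <- sig / (width(regions) / 1e3) / (librarySize / 1e6)
  names(rpkm) <- if (!is.null(names(regions))) names(regions)
                 else if (!is.null(regions$gene_id)) regions$gene_id
                 else NULL
  rpkm
}

#' Build a paired region-by-sample signal matrix
#'
#' @param tracks named list of coverage `GRanges` (e.g.
#'   `list(DRIP = ..., DRIP_RH = ...)`).
#' @param regions `GRanges` of regions, identical rows for every sample.
#' @param librarySizes optional numeric vector (one per track); defaults to
#'   each track's total signal.
#' @return numeric matrix, rows = regions, columns = samples.
#' @export
signalMatrix <- function(tracks, regions, librarySizes = NULL) {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  if (is.null(librarySizes)) librarySizes <- rep(list(NULL), length(tracks))
  cols <- mapply(function(tr, lib) rpkmOverRegions(tr, regions, lib),
                 tracks, librarySizes, SIMPLIFY = FALSE)
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(tracks)
  mat
}

#' Paired comparison of two signal columns (Wilcoxon signed-rank)
#'
#' Tests per-region differences between two paired samples (by default
#' column 1 minus column 2, e.g. DRIP minus DRIP+RH). Zero differences are
#' dropped per the Wilcoxon convention; the exact null is used for up to 25
#' non-zero differences, otherwise the tie-corrected normal approximation.
#' The default alternative "greater" asks whether the first sample carries
#' more signal.
#'
#' @param mat matrix from [signalMatrix()] (>= 2 columns).
#' @param alternative "greater" (default) or "two.sided".
#' @param columns length-2 index/name vector selecting the pair.
#' @return a list with `statistic` (V), `p.value`, `n` (non-zero pairs),
#'   `alternative` and `method`.
#' @export
pairedSignalTest <- function(mat, alternative = c("greater", "two.sided"),
                             columns = c(1, 2)) {
  alternative <- match.arg(alternative)
  stopifnot(ncol(mat) >= 2)
  a <- mat[, columns[1]]
  b <- mat[, columns[2]]
  d <- a - b
  nz <- sum(d != 0)
  if (nz == 0L) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p.value = 1, n = 0L,
                alternative = alternative,
                method = "Wilcoxon signed rank (degenerate)"))
  }
  if (nz < 6L)
    warning("fewer than 6 non-zero differences; p value is coarse")
  ht <- suppressWarnings(
    wilcox.test(a, b, paired = TRUE, alternative = alternative,
                exact = nz <= 25, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value, n = nz,
       alternative = alternative, method = ht$method)
}
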