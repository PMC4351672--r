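#' Subtract germline variants from a tumor mutation catalog
#'
#' Removes every tumor record that matches a normal-tissue record of the
#' same patient, same class, at the same position (within `window` bp).
#' Idempotent; an empty normal set returns the tumor catalog unchanged.
#'
#' @param tumor,normal mutation `GRanges` from [readMutationCatalog()].
#' @param window positional tolerance in bp (default 0, exact match).
#' @return the retained tumor records.
#' @export
subtractGermline <- function(tumor, normal, window = 0) {
  if (!length(normal) || !length(tumor)) return(tumor)
  hits <- findOverlaps(tumor, normal, maxgap = window, ignore.strand = TRUE)
  same <- tumor$patient_id[queryHits(hits)] == normal$patient_id[subjectHits(hits)] &
          tumor$mclass[queryHits(hits)] == normal$mclass[subjectHits(hits)]
  drop <- unique(queryHits(hits)[same])
  if (length(drop)) tumor[-drop] else tumor
}

#' Per-gene, per-patient regional mutation hits
#'
#' For one mutation class, tabulates whether (or how often) each patient's
#' mutations fall inside each gene's region. Region ends are inclusive of
#' their last base; a record one base past the region is not a hit.
#' Rearrangement breakpoints each count individually, so a rearrangement
#' hits a region if either breakpoint falls inside it.
#'
#' @param records mutation `GRanges` (columns `patient_id`, `mclass`).
#' @param regions `GRanges` of one region per gene (with `gene_id`).
#' @param cohort named character vector mapping patient to group; defines
#'   the full patient set so patients without mutations keep zero rows.
#' @param mclass mutation class to count ("SBM", "indel" or
#'   "rearrangement").
#' @param binarize if `TRUE` (default) entries are 0/1 = patient has >= 1
#'   hit; if `FALSE`, raw per-region counts.
#' @return integer matrix, rows = genes, columns = patients.
#' @export
countRegionHits <- function(records, regions, cohort,
                            mclass = c("SBM", "indel", "rearrangement"),
                            binarize = TRUE) {
  mclass <- match.arg(mclass)
  patients <- names(cohort)
  geneIds <- if (!is.null(regions$gene_id)) regions$gene_id else names(regions)
  mat <- matrix(0L, nrow = length(regions), ncol = length(patients),
                dimnames = list(geneIds, patients))
  rec <- records[records$mclass == mclass]
  if (length(rec)) {
    unknown <- setdiff(unique(rec$patient_id), patients)
    if (length(unknown))
      warning("mutation records for patient(s) outside the cohort ignored: ",
              paste(unknown, collapse = ", "))
    rec <- rec[rec$patient_id %in% patients]
    hits <- findOverlaps(rec, regions, ignore.strand = TRUE)
    if (length(hits)) {
      idx <- cbind(subjectHits(hits),
                   match(rec$patient_id[queryHits(hits)], patients))
      counts <- table(idx[, 1], idx[, 2])
      mat[cbind(as.integer(rownames(counts))[row(counts)],
                as.integer(colnames(counts))[col(counts)])] <-
        as.integer(counts)
    }
  }
  if (binarize) mat <- (mat > 0L) * 1L
  mat
}

#' Stratified one-tailed Cochran-Mantel-Haenszel Z effect size
#'
#' Compares regional mutation hits between two patient groups, stratifying
#' by gene. In the default "binary" variant each stratum is the 2x2 table of
#' group membership against "patient has >= 1 hit in this gene's region":
#' with `a_k` hit patients in group A, `m_k` hit patients overall,
#' `N = n_A + n_B`,
#' \deqn{Z = \sum_k (a_k - E_k) / \sqrt{\sum_k V_k},\quad
#'       E_k = n_A m_k / N,\quad
#'       V_k = n_A n_B m_k (N - m_k) / (N^2 (N - 1)).}
#' Strata with `m_k = 0` or `m_k = N` are uninformative and contribute
#' nothing. Positive Z means enrichment in group A;
#' `p = 1 - pnorm(Z)` (one-tailed, no continuity correction).
#'
#' The "count" variant uses raw per-stratum mutation counts instead of the
#' binarized indicator: given the stratum total `T_k`, each count is
#' allocated to group A with probability `n_A / N` under the null, so
#' `E_k = T_k n_A / N` and `V_k = T_k (n_A / N)(n_B / N)`. Binarization is
#' the default because it is robust to hypermutated patients.
#'
#' @param hits matrix from [countRegionHits()] (binary for the default
#'   variant, raw counts with `binarize = FALSE` for the count variant).
#' @param cohort named character vector mapping patient to group.
#' @param groupA,groupB group labels to compare (A is the putatively
#'   enriched group).
#' @param variant "binary" (default) or "count".
#' @return a [CMHResult-class]. When no stratum is informative the result
#'   is flagged degenerate with `p = 1`.
#' @examples
#' hits <- matrix(c(1, 0), nrow = 1, dimnames = list("g1", c("p1", "p2")))
#' cmhZ(hits, c(p1 = "BRCA1", p2 = "sporadic"), "BRCA1", "sporadic")
#' @export
cmhZ <- function(hits, cohort, groupA, groupB,
                 variant = c("binary", "count")) {
  variant <- match.arg(variant)
  pa <- names(cohort)[cohort == groupA]
  pb <- names(cohort)[cohort == groupB]
  if (!length(pa) || !length(pb))
    stop("both groups must contain at least one patient")
  ha <- hits[, pa, drop = FALSE]
  hb <- hits[, pb, drop = FALSE]
  nA <- length(pa); nB <- length(pb); N <- nA + nB
  if (variant == "binary") {
    ha <- (ha > 0L) * 1L; hb <- (hb > 0L) * 1L
    a <- rowSums(ha); m <- a + rowSums(hb)
    informative <- m > 0 & m < N
    E <- nA * m / N
    V <- nA * nB * m * (N - m) / (N^2 * (N - 1))
  } else {
    a <- rowSums(ha); m <- a + rowSums(hb)
    informative <- m > 0
    E <- m * nA / N
    V <- m * (nA / N) * (nB / N)
  }
  strata <- S4Vectors::DataFrame(gene_id = rownames(hits), a = a, m = m,
                                 E = E, V = V)[informative, , drop = FALSE]
  sumV <- sum(V[informative])
  if (sumV <= 0) {
    return(new("CMHResult", z = NA_real_, p = 1, strata = strata,
               groups = c(groupA, groupB), variant = variant,
               degenerate = TRUE))
  }
  z <- sum(a[informative] - E[informative]) / sqrt(sumV)
  new("CMHResult", z = z, p = pnorm(z, lower.tail = FALSE), strata = strata,
      groups = c(groupA, groupB), variant = variant, degenerate = FALSE)
}

#' Effect-size panel across regions, gene sets, classes and comparisons
#'
#' Runs [cmhZ()] for every combination of region definition (whole-gene
#' region of interest and/or symmetric TTS window), gene set (TR-bound genes
#' and, when given, an R-loop-free negative control set), mutation class,
#' and group comparison (each mutant group against the sporadic/wild-type
#' group by default).
#'
#' @param records mutation `GRanges` (germline-subtracted).
#' @param genes stranded gene models for all genes of interest.
#' @param cohort named character vector mapping patient to group.
#' @param trGenes character vector of TR-bound gene ids.
#' @param negGenes optional character vector of negative-control gene ids.
#' @param regionTypes subset of `c("whole_gene", "tts_window")`.
#' @param comparisons list of `c(groupA, groupB)` pairs.
#' @param classes mutation classes to analyse.
#' @param variant passed to [cmhZ()].
#' @param wholeGeneUp,wholeGeneDown,ttsFlank region parameters in bp.
#' @param genome optional genome for region clipping.
#' @return a `data.frame` with one row per panel cell (`region`,
#'   `gene_set`, `mclass`, `comparison`, `z`, `p`, `n_informative`,
#'   `degenerate`); the full [CMHResult-class] objects are attached as
#'   `attr(x, "results")`, keyed `region.gene_set.mclass.groupA_vs_groupB`.
#' @export
effectSizePanel <- function(records, genes, cohort, trGenes,
                            negGenes = NULL,
                            regionTypes = c("whole_gene", "tts_window"),
                            comparisons = list(c("BRCA1", "sporadic"),
                                               c("BRCA2", "sporadic")),
                            classes = c("SBM", "indel", "rearrangement"),
                            variant = "binary",
                            wholeGeneUp = 1250, wholeGeneDown = 5000,
                            ttsFlank = 4000, genome = NULL) {
  regionTypes <- match.arg(regionTypes, several.ok = TRUE)
  geneSets <- list(TR = trGenes)
  if (!is.null(negGenes)) geneSets$negative <- negGenes
  rows <- list(); results <- list()
  for (rt in regionTypes) {
    for (gs in names(geneSets)) {
      sel <- genes[genes$gene_id %in% geneSets[[gs]]]
      if (!length(sel)) next
      regions <- switch(rt,
        whole_gene = wholeGeneRegions(sel, wholeGeneUp, wholeGeneDown,
                                      genome = genome),
        tts_window = ttsWindows(sel, ttsFlank, genome = genome))
      for (cl in classes) {
        hitsMat <- countRegionHits(records, regions, cohort, mclass = cl,
                                   binarize = (variant == "binary"))
        for (cmp in comparisons) {
          res <- cmhZ(hitsMat, cohort, cmp[1], cmp[2], variant = variant)
          key <- paste(rt, gs, cl, paste0(cmp[1], "_vs_", cmp[2]), sep = ".")
          results[[key]] <- res
          rows[[key]] <- data.frame(
            region = rt, gene_set = gs, mclass = cl,
            comparison = paste0(cmp[1], "_vs_", cmp[2]),
            z = res@z, p = res@p,
            n_informative = nrow(res@strata),
            degenerate = res@degenerate,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  attr(panel, "results") <- results
  panel
}

#' Distance from mutation records to the nearest peak
#'
#' 0 when the record position lies inside a peak, otherwise the number of
#' bases between the position and the nearest peak edge on the same
#' chromosome. Records on chromosomes without any peak get `NA` with a
#' warning.
#'
#' @param records mutation `GRanges`.
#' @param peaks peak `GRanges`.
#' @return numeric vector of distances, one per record.
#' @export
distanceToNearestPeak <- function(records, peaks) {
  out <- rep(NA_real_, length(records))
  # distanceToNearest warns when query chromosomes carry no peaks at all;
  # that case is reported below with a clearer message
  hits <- suppressWarnings(
    distanceToNearest(records, peaks, ignore.strand = TRUE))
  out[queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  if (anyNA(out))
    warning(sum(is.na(out)),
            " record(s) on chromosomes without peaks: distance undefined")
  out
}
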