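#' Run the termination-region discovery analysis end to end
#'
#' Executes the peak-to-TR stages in order: (1) TR overlap of the full peak
#' set with the uniform-placement enrichment test; (2) removal of peaks
#' overlapping promoters or transcript spans, and re-testing; (3)
#' restriction to TRs of expressed genes, yielding the TR gene table; (4)
#' expression comparison of TR-bound vs unbound genes; (5) co-localization
#' of the retained TR peaks with a second peak set (e.g. elongating RNAPII)
#' under the chromosome-aware shuffle null; (6) paired DRIP vs DRIP+RH
#' comparison over the retained TR peak intervals. Stages whose inputs are
#' not supplied are skipped and reported as `NULL`.
#'
#' @param genes stranded gene models (`GRanges` with `gene_id`).
#' @param peaks primary peak set (`GRanges`).
#' @param genome Seqinfo / named lengths / chrom.sizes path.
#' @param rnapiiPeaks optional second peak set for co-localization.
#' @param expression optional named numeric expression vector.
#' @param dripTracks optional named list of two coverage tracks
#'   (DRIP first, DRIP+RH second).
#' @param dripLibrarySizes optional numeric vector matching `dripTracks`.
#' @param trLength,promoterUpstream region parameters (bp).
#' @param expressedThreshold expression cutoff for stage 3.
#' @param nShuffles,seed shuffle-null parameters.
#' @return a list of class `trDiscoveryReport`: `stages` (per-stage counts
#'   and results), `trGeneTable`, `params`.
#' @export
runTRDiscovery <- function(genes, peaks, genome,
                           rnapiiPeaks = NULL, expression = NULL,
                           dripTracks = NULL, dripLibrarySizes = NULL,
                           trLength = 4000, promoterUpstream = 1250,
                           expressedThreshold = 1,
                           nShuffles = 1000, seed = 1) {
  si <- .asSeqinfo(genome)
  trs <- terminationRegions(genes, length = trLength, genome = si)
  stages <- list()

  ## stage 1: raw TR overlap
  stages$tr_overlap <- poissonOverlapTest(peaks, trs, si)

  ## stage 2: promoter/transcript exclusion filter
  proms <- promoterRegions(genes, upstream = promoterUpstream, genome = si)
  kept <- filterPeaks(peaks, list(proms, granges(genes)))
  stages$filtered <- poissonOverlapTest(kept, trs, si)

  ## stage 3: expressed-gene TRs
  if (!is.null(expression)) {
    expressedIds <- classifyExpressed(expression, expressedThreshold)
    exprTrs <- trs[trs$gene_id %in% expressedIds]
    stages$expressed_filtered <- poissonOverlapTest(kept, exprTrs, si)
  } else {
    stages$expressed_filtered <- NULL
  }

  trTable <- trGeneTable(kept, genes, trLength = trLength,
                         expression = expression,
                         threshold = expressedThreshold, genome = si)
  trGenes <- unique(trTable$gene_id)

  ## stage 4: expression comparison of TR vs non-TR genes
  stages$expression_test <- if (!is.null(expression)) {
    inTR <- names(expression) %in% trGenes
    if (any(inTR) && any(!inTR))
      compareExpression(expression[inTR], expression[!inTR])
    else NULL
  } else NULL

  ## stage 5: RNAPII co-localization of the retained TR peaks
  trPeakNames <- unique(trTable$peak)
  trPeaks <- kept[names(kept) %in% trPeakNames]
  stages$rnapii <- if (!is.null(rnapiiPeaks) && length(trPeaks)) {
    list(fraction = countOverlappingPeaks(trPeaks, rnapiiPeaks)@observed /
                    length(trPeaks),
         shuffle = shuffleEnrichment(trPeaks, rnapiiPeaks, si,
                                     nShuffles = nShuffles, seed = seed))
  } else NULL

  ## stage 6: paired DRIP comparison over the TR peak intervals
  stages$drip <- if (!is.null(dripTracks) && length(trPeaks)) {
    mat <- signalMatrix(dripTracks, trPeaks,
                        librarySizes = dripLibrarySizes)
    list(matrix = mat, test = pairedSignalTest(mat))
  } else NULL

  structure(list(
    stages = stages,
    counts = c(
      n_peaks = length(peaks),
      tr_overlapping = stages$tr_overlap@observed,
      filtered = stages$filtered@observed,
      expressed_filtered = if (!is.null(stages$expressed_filtered))
        stages$expressed_filtered@observed else NA_integer_,
      tr_peaks = length(trPeaks),
      tr_genes = length(trGenes)),
    trGeneTable = trTable,
    trGenes = trGenes,
    params = list(trLength = trLength, promoterUpstream = promoterUpstream,
                  expressedThreshold = expressedThreshold,
                  nShuffles = nShuffles, seed = seed)),
    class = "trDiscoveryReport")
}

#' @export
print.trDiscoveryReport <- function(x, ...) {
  cat("TR discovery report\n")
  cat("  peaks:", x$counts[["n_peaks"]],
      "| overlapping a TR:", x$counts[["tr_overlapping"]],
      "| after promoter/transcript filter:", x$counts[["filtered"]],
      "| in expressed TRs:", x$counts[["expressed_filtered"]], "\n")
  cat("  TR peaks:", x$counts[["tr_peaks"]],
      "-> TR genes:", x$counts[["tr_genes"]], "\n")
  invisible(x)
}

#' Run the regional mutation effect-size analysis end to end
#'
#' Subtracts germline records when supplied, then computes the CMH
#' effect-size panel over both region definitions, both gene sets and all
#' mutation classes, and annotates each indel of the enriched group with
#' its distance to the nearest peak.
#'
#' @param records somatic mutation `GRanges`.
#' @param cohort named character vector mapping patient to group.
#' @param genes stranded gene models.
#' @param trGenes character vector of TR-bound gene ids.
#' @param negGenes optional negative-control gene ids.
#' @param normalRecords optional germline records to subtract.
#' @param peaks optional peak `GRanges` for indel distance annotation.
#' @param indelGroup group whose indels are annotated (default "BRCA1").
#' @param ... passed to [effectSizePanel()].
#' @return a list of class `mutationPanelReport`: `panel`,
#'   `indelDistances` (data.frame or NULL), `nCells`.
#' @export
runMutationPanel <- function(records, cohort, genes, trGenes,
                             negGenes = NULL, normalRecords = NULL,
                             peaks = NULL, indelGroup = "BRCA1", ...) {
  if (!is.null(normalRecords))
    records <- subtractGermline(records, normalRecords)
  panel <- effectSizePanel(records, genes, cohort, trGenes,
                           negGenes = negGenes, ...)
  indelDistances <- NULL
  if (!is.null(peaks)) {
    sel <- records[records$mclass == "indel" &
                   cohort[records$patient_id] == indelGroup]
    sel <- sel[!is.na(sel$patient_id)]
    if (length(sel)) {
      trRegions <- suppressWarnings(
        ttsWindows(genes[genes$gene_id %in% trGenes]))
      inTR <- overlapsAny(sel, trRegions, ignore.strand = TRUE)
      sel <- sel[inTR]
    }
    if (length(sel)) {
      d <- suppressWarnings(distanceToNearestPeak(sel, peaks))
      indelDistances <- data.frame(
        patient_id = sel$patient_id,
        chrom = as.character(seqnames(sel)),
        pos = start(sel),
        distance_to_peak = d,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(panel = panel, indelDistances = indelDistances,
                 nCells = nrow(panel)),
            class = "mutationPanelReport")
}

#' @export
print.mutationPanelReport <- function(x, ...) {
  cat("Mutation effect-size panel (", x$nCells, " cells; ",
      "no multiplicity correction applied)\n", sep = "")
  print(x$panel, digits = 3)
  invisible(x)
}

#' Write machine-readable reports
#'
#' Serialises a TR-discovery and/or mutation-panel report to a directory:
#' TSV tables (TR gene table, panel, indel distances) plus one versioned
#' JSON summary with every count, statistic, seed and parameter.
#'
#' @param dir output directory.
#' @param trReport optional result of [runTRDiscovery()].
#' @param mutReport optional result of [runMutationPanel()].
#' @return path of the JSON summary, invisibly.
#' @export
writeReport <- function(dir, trReport = NULL, mutReport = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(schema = "termloop-report/1",
                  generated = "termloop",
                  version = as.character(utils::packageVersion("termloop")))
  if (!is.null(trReport)) {
    write.table(as.data.frame(trReport$trGeneTable),
                file.path(dir, "tr_gene_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    st <- trReport$stages
    ovl <- function(o) if (is.null(o)) NULL else
      list(observed = o@observed, n_peaks = o@nPeaks, lambda = o@lambda,
           p = o@pValue, method = o@method)
    summary$tr_discovery <- list(
      counts = as.list(trReport$counts),
      tr_overlap = ovl(st$tr_overlap),
      filtered = ovl(st$filtered),
      expressed_filtered = ovl(st$expressed_filtered),
      expression_test = st$expression_test[c("statistic", "p.value")],
      rnapii = if (!is.null(st$rnapii)) list(
        fraction = st$rnapii$fraction,
        fold_enrichment = st$rnapii$shuffle@foldEnrichment,
        empirical_p = st$rnapii$shuffle@empiricalP,
        n_shuffles = st$rnapii$shuffle@nShuffles,
        seed = st$rnapii$shuffle@seed),
      drip = if (!is.null(st$drip))
        st$drip$test[c("statistic", "p.value", "n")],
      params = trReport$params)
  }
  if (!is.null(mutReport)) {
    write.table(mutReport$panel, file.path(dir, "mutation_panel.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(mutReport$indelDistances))
      write.table(mutReport$indelDistances,
                  file.path(dir, "indel_distances.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    summary$mutation_panel <- list(
      n_cells = mutReport$nCells,
      cells = mutReport$panel)
  }
  out <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, out, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null")
  invisible(out)
}
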