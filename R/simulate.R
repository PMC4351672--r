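# Generator seed offsets: each generator draws from seed + offset so adding
# one generator never perturbs another's stream.
.SEED_OFFSETS <- c(genome = 101L, peaks = 211L, expression = 307L,
                   signal = 401L, mutations = 503L)

#' Create a simulation configuration
#'
#' Constructor for [SimulationConfig-class]. Defaults state a desk-scale
#' world: one 10 Mb chromosome carrying 200 non-overlapping genes, 500
#' peaks of which 30% are planted in termination regions, a 21-patient
#' cohort (12 sporadic, 5 BRCA1, 4 BRCA2), log-normal expression with a
#' 2-fold boost for TR genes, DRIP signal depleted 0.3-fold by RNaseH, and
#' per-class mutation rates chosen so a TTS +/- 4 kb window has about a 5%
#' per-patient hit probability. See the vignette for the rationale.
#'
#' @param seed master RNG seed.
#' @param nChroms,chromLength genome layout.
#' @param nGenes,geneLengthRange,minFlank gene placement parameters (bp).
#' @param nPeaks,fracPeaksInTR,peakLengthRange peak parameters.
#' @param exprMeanlog,exprSdlog,trBoost,silentFraction expression model.
#' @param signalMean,rhFactor,backgroundSignal DRIP signal model.
#' @param cohortSizes named integer vector (sporadic, BRCA1, BRCA2).
#' @param mutationRates named per-Mb rates for SBM, indel, rearrangement.
#' @param theta named list: `theta[[group]][[class]]` rate ratio inside the
#'   designated regions of TR genes (defaults to 1 everywhere).
#' @return a validated `SimulationConfig`.
#' @examples
#' simulationConfig(seed = 7, nGenes = 50L)
#' @export
simulationConfig <- function(seed = 1L,
                             nChroms = 1L,
                             chromLength = 1e7,
                             nGenes = 200L,
                             geneLengthRange = c(2000, 10000),
                             minFlank = 10000,
                             nPeaks = 500L,
                             fracPeaksInTR = 0.3,
                             peakLengthRange = c(150, 500),
                             exprMeanlog = 1,
                             exprSdlog = 1,
                             trBoost = 2,
                             silentFraction = 0.3,
                             signalMean = 50,
                             rhFactor = 0.3,
                             backgroundSignal = 1,
                             cohortSizes = c(sporadic = 12L, BRCA1 = 5L,
                                             BRCA2 = 4L),
                             mutationRates = c(SBM = 6.4, indel = 6.4,
                                               rearrangement = 3.2),
                             theta = list()) {
  groups <- c("sporadic", "BRCA1", "BRCA2")
  classes <- c("SBM", "indel", "rearrangement")
  full <- lapply(setNames(groups, groups), function(g)
    setNames(rep(1, length(classes)), classes))
  for (g in names(theta)) {
    if (!g %in% groups) stop("unknown group in theta: ", g)
    for (cl in names(theta[[g]])) {
      if (!cl %in% classes) stop("unknown class in theta: ", cl)
      full[[g]][[cl]] <- theta[[g]][[cl]]
    }
  }
  new("SimulationConfig",
      seed = as.integer(seed), nChroms = as.integer(nChroms),
      chromLength = chromLength, nGenes = as.integer(nGenes),
      geneLengthRange = geneLengthRange, minFlank = minFlank,
      nPeaks = as.integer(nPeaks), fracPeaksInTR = fracPeaksInTR,
      peakLengthRange = peakLengthRange,
      exprMeanlog = exprMeanlog, exprSdlog = exprSdlog, trBoost = trBoost,
      silentFraction = silentFraction,
      signalMean = signalMean, rhFactor = rhFactor,
      backgroundSignal = backgroundSignal,
      cohortSizes = setNames(as.integer(cohortSizes), names(cohortSizes)),
      mutationRates = mutationRates, theta = full)
}

#' Simulate a genome with non-overlapping gene models
#'
#' Genes are assigned to chromosomes uniformly, given uniform lengths, and
#' placed left to right with at least `minFlank` bp between neighbours and
#' chromosome ends; leftover space is spread randomly over the gaps.
#' Strands are Bernoulli(0.5). Deterministic for a fixed config seed.
#'
#' @param config a [SimulationConfig-class].
#' @return a list with `genes` (stranded `GRanges` with `gene_id`,
#'   seqlengths attached), `seqinfo`, and `truth` (a data.frame of gene_id,
#'   chrom, start, end, strand, tss, tts).
#' @export
simulateGenome <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  si <- Seqinfo(sprintf("chr%d", seq_len(config@nChroms)),
                rep(as.integer(config@chromLength), config@nChroms))
  withr::with_seed(config@seed + .SEED_OFFSETS[["genome"]], {
    chromOf <- sort(sample.int(config@nChroms, config@nGenes, replace = TRUE))
    lens <- floor(runif(config@nGenes, config@geneLengthRange[1],
                        config@geneLengthRange[2] + 1))
    starts <- integer(config@nGenes)
    for (ch in unique(chromOf)) {
      idx <- which(chromOf == ch)
      n <- length(idx)
      slack <- config@chromLength - sum(lens[idx]) - (n + 1) * config@minFlank
      if (slack < 0)
        stop("genes are not placeable: chromosome ", ch,
             " too short for ", n, " genes with ", config@minFlank,
             " bp flanks")
      cuts <- sort(runif(n))
      gaps <- diff(c(0, cuts, 1)) * slack
      pos <- cumsum(config@minFlank + gaps[seq_len(n)] +
                    c(0, lens[idx][-n])) + 1
      starts[idx] <- floor(pos)
    }
    strands <- ifelse(runif(config@nGenes) < 0.5, "+", "-")
  })
  genes <- GRanges(sprintf("chr%d", chromOf),
                   IRanges(starts, width = lens), strand = strands,
                   gene_id = sprintf("g%03d", seq_len(config@nGenes)),
                   seqinfo = si)
  names(genes) <- genes$gene_id
  truth <- data.frame(gene_id = genes$gene_id,
                      chrom = as.character(seqnames(genes)),
                      start = start(genes), end = end(genes),
                      strand = as.character(strand(genes)),
                      tss = unname(geneTSS(genes)),
                      tts = unname(geneTTS(genes)),
                      stringsAsFactors = FALSE)
  list(genes = genes, seqinfo = si, truth = truth)
}

#' Simulate ChIP-seq peaks preferentially placed in termination regions
#'
#' `floor(fracPeaksInTR * nPeaks)` peaks are placed uniformly inside
#' randomly chosen gene TRs (fully contained); the remainder are placed
#' uniformly over the genome (start uniform on the chromosome, extent
#' clipped at its end). The placement label is recorded as truth.
#'
#' @param config a [SimulationConfig-class].
#' @param genes gene models from [simulateGenome()].
#' @param trLength TR length in bp.
#' @return a list with `peaks` (sorted `GRanges`, `in_tr` label column) and
#'   `truth` (data.frame of peak name, placement label, target gene).
#' @export
simulatePeaks <- function(config, genes, trLength = 4000) {
  stopifnot(is(config, "SimulationConfig"))
  si <- seqinfo(genes)
  trs <- suppressWarnings(terminationRegions(genes, length = trLength,
                                             genome = si))
  nTR <- floor(config@fracPeaksInTR * config@nPeaks)
  nBG <- config@nPeaks - nTR
  withr::with_seed(config@seed + .SEED_OFFSETS[["peaks"]], {
    lens <- floor(runif(config@nPeaks, config@peakLengthRange[1],
                        config@peakLengthRange[2] + 1))
    targetGene <- rep(NA_character_, config@nPeaks)
    chrom <- character(config@nPeaks)
    start <- numeric(config@nPeaks)
    if (nTR > 0) {
      pick <- sample(length(trs), nTR, replace = TRUE)
      room <- width(trs)[pick] - lens[seq_len(nTR)]
      if (any(room < 0)) {  # peak longer than (possibly clipped) TR
        lens[seq_len(nTR)][room < 0] <- width(trs)[pick][room < 0]
        room <- pmax(room, 0)
      }
      start[seq_len(nTR)] <- start(trs)[pick] + floor(runif(nTR) * (room + 1))
      chrom[seq_len(nTR)] <- as.character(seqnames(trs))[pick]
      targetGene[seq_len(nTR)] <- trs$gene_id[pick]
    }
    if (nBG > 0) {
      chromLens <- seqlengths(si)
      pickChr <- sample(length(chromLens), nBG, replace = TRUE,
                        prob = chromLens / sum(chromLens))
      idx <- nTR + seq_len(nBG)
      chrom[idx] <- names(chromLens)[pickChr]
      start[idx] <- floor(runif(nBG) * chromLens[pickChr]) + 1
    }
  })
  ends <- pmin(start + lens - 1, seqlengths(si)[chrom])
  peaks <- GRanges(chrom, IRanges(start, ends),
                   name = sprintf("peak_%03d", seq_len(config@nPeaks)),
                   in_tr = seq_len(config@nPeaks) <= nTR,
                   target_gene = targetGene,
                   seqinfo = si)
  names(peaks) <- peaks$name
  peaks <- sort(peaks, ignore.strand = TRUE)
  list(peaks = peaks,
       truth = data.frame(peak = peaks$name, in_tr = peaks$in_tr,
                          target_gene = peaks$target_gene,
                          stringsAsFactors = FALSE))
}

#' Simulate a gene expression table
#'
#' Log-normal values; genes in `trGeneIds` are multiplied by `trBoost`, and
#' an exact `silentFraction` share of the non-TR genes is set to zero.
#'
#' @param config a [SimulationConfig-class].
#' @param geneIds character vector of gene ids.
#' @param trGeneIds subset of `geneIds` designated TR-bound.
#' @return a list with `expression` (named numeric) and `truth`
#'   (data.frame of gene_id, tr_gene, silent).
#' @export
simulateExpression <- function(config, geneIds, trGeneIds = character(0)) {
  stopifnot(is(config, "SimulationConfig"))
  n <- length(geneIds)
  isTR <- geneIds %in% trGeneIds
  withr::with_seed(config@seed + .SEED_OFFSETS[["expression"]], {
    vals <- rlnorm(n, config@exprMeanlog, config@exprSdlog)
    vals[isTR] <- vals[isTR] * config@trBoost
    nonTR <- which(!isTR)
    silent <- sample(nonTR, round(config@silentFraction * length(nonTR)))
    vals[silent] <- 0
  })
  names(vals) <- geneIds
  list(expression = vals,
       truth = data.frame(gene_id = geneIds, tr_gene = isTR,
                          silent = seq_len(n) %in% silent,
                          stringsAsFactors = FALSE))
}

#' Simulate paired DRIP and DRIP+RH coverage tracks
#'
#' Per-region counts are Poisson(`signalMean`); the RNaseH-treated track
#' uses mean `signalMean * rhFactor`. Each region becomes one bedGraph
#' interval whose per-base score times width equals the planted count, so
#' planted RPKMs round-trip exactly. Low-level background intervals are
#' scattered over the inter-region gaps.
#'
#' @param config a [SimulationConfig-class].
#' @param regions `GRanges` of signal regions (e.g. TR peak intervals).
#' @return a list with `drip` and `dripRH` (score `GRanges`), `truth`
#'   (data.frame of region, width, drip_count, rh_count) and
#'   `librarySizes`.
#' @export
simulateSignal <- function(config, regions) {
  stopifnot(is(config, "SimulationConfig"))
  if (!isDisjoint(regions, ignore.strand = TRUE)) {
    # overlapping candidate regions would break bedGraph semantics; signal
    # is simulated over their merged footprint instead
    regions <- reduce(granges(regions), ignore.strand = TRUE)
    names(regions) <- sprintf("region_%d", seq_along(regions))
  }
  n <- length(regions)
  regionIds <- if (!is.null(names(regions))) names(regions)
               else sprintf("region_%d", seq_len(n))
  withr::with_seed(config@seed + .SEED_OFFSETS[["signal"]], {
    dripCount <- rpois(n, config@signalMean)
    rhCount <- rpois(n, config@signalMean * config@rhFactor)
    gapRanges <- gaps(reduce(granges(regions), ignore.strand = TRUE))
    gapRanges <- gapRanges[strand(gapRanges) == "*" & width(gapRanges) >= 1000]
    nbg <- min(2L * n, length(gapRanges))
    bg <- if (nbg > 0) {
      pick <- sample(length(gapRanges), nbg)
      w <- pmin(500L, width(gapRanges)[pick])
      off <- floor(runif(nbg) * (width(gapRanges)[pick] - w + 1))
      GRanges(seqnames(gapRanges)[pick],
              IRanges(start(gapRanges)[pick] + off, width = w),
              seqinfo = seqinfo(regions))
    } else GRanges(seqinfo = seqinfo(regions))
    bgDrip <- rpois(nbg, config@backgroundSignal)
    bgRH <- rpois(nbg, config@backgroundSignal)
  })
  mkTrack <- function(counts, bgCounts) {
    main <- granges(regions)
    strand(main) <- "*"
    main$score <- counts / width(main)
    bgt <- bg
    bgt$score <- bgCounts / width(bgt)
    tr <- sort(c(main, bgt), ignore.strand = TRUE)
    tr[tr$score > 0]
  }
  list(drip = mkTrack(dripCount, bgDrip),
       dripRH = mkTrack(rhCount, bgRH),
       truth = data.frame(region = regionIds, width = width(regions),
                          drip_count = dripCount, rh_count = rhCount,
                          stringsAsFactors = FALSE),
       librarySizes = c(drip = sum(dripCount) + sum(bgDrip),
                        dripRH = sum(rhCount) + sum(bgRH)))
}

#' Simulate per-patient somatic mutation catalogs
#'
#' Each patient receives, per mutation class, a genome-wide uniform Poisson
#' process at the class base rate; within the designated regions of the TR
#' genes, the rate is multiplied by `theta[[group]][[class]]` (implemented
#' by superposing an extra Poisson process at rate `(theta - 1) * base`
#' there). Rearrangements are emitted as single-breakpoint records.
#'
#' @param config a [SimulationConfig-class].
#' @param genes gene models from [simulateGenome()].
#' @param trGeneIds gene ids whose regions carry the planted rate ratio.
#' @param regionType region definition carrying the planted effect,
#'   "tts_window" (default) or "whole_gene".
#' @return a list with `mutations` (`GRanges` with `patient_id`, `mclass`),
#'   `cohort` (named character vector), and `truth` (config echo plus
#'   per-patient counts).
#' @export
simulateMutations <- function(config, genes, trGeneIds,
                              regionType = c("tts_window", "whole_gene")) {
  stopifnot(is(config, "SimulationConfig"))
  regionType <- match.arg(regionType)
  si <- seqinfo(genes)
  sel <- genes[genes$gene_id %in% trGeneIds]
  regions <- suppressWarnings(switch(regionType,
    tts_window = ttsWindows(sel, genome = si),
    whole_gene = wholeGeneRegions(sel, genome = si)))
  regions <- reduce(granges(regions), ignore.strand = TRUE)
  regionBp <- sum(as.numeric(width(regions)))
  chromLens <- seqlengths(si)
  G <- sum(as.numeric(chromLens))
  cohort <- setNames(
    rep(names(config@cohortSizes), config@cohortSizes),
    sprintf("%s_%02d", rep(names(config@cohortSizes), config@cohortSizes),
            unlist(lapply(config@cohortSizes, seq_len))))
  classes <- names(config@mutationRates)
  withr::with_seed(config@seed + .SEED_OFFSETS[["mutations"]], {
    recs <- list()
    for (p in names(cohort)) {
      grp <- cohort[[p]]
      for (cl in classes) {
        rate <- config@mutationRates[[cl]] / 1e6   # per bp
        nBase <- rpois(1, rate * G)
        posChr <- sample(length(chromLens), nBase, replace = TRUE,
                         prob = chromLens / sum(chromLens))
        pos <- floor(runif(nBase) * chromLens[posChr]) + 1
        chr <- names(chromLens)[posChr]
        th <- config@theta[[grp]][[cl]]
        if (th > 1 && regionBp > 0) {
          nExtra <- rpois(1, (th - 1) * rate * regionBp)
          if (nExtra > 0) {
            pickReg <- sample(length(regions), nExtra, replace = TRUE,
                              prob = width(regions) / regionBp)
            extraPos <- start(regions)[pickReg] +
              floor(runif(nExtra) * width(regions)[pickReg])
            pos <- c(pos, extraPos)
            chr <- c(chr, as.character(seqnames(regions))[pickReg])
          }
        }
        if (length(pos))
          recs[[paste(p, cl)]] <- data.frame(
            patient_id = p, chrom = chr, pos = pos, mclass = cl,
            stringsAsFactors = FALSE)
      }
    }
  })
  df <- do.call(rbind, recs)
  mutations <- if (is.null(df)) {
    GRanges(seqinfo = si)
  } else {
    gr <- GRanges(df$chrom, IRanges(df$pos, width = 1L),
                  patient_id = df$patient_id, mclass = df$mclass,
                  ref = NA_character_, alt = NA_character_, seqinfo = si)
    sort(gr, ignore.strand = TRUE)
  }
  theta <- config@theta
  list(mutations = mutations, cohort = cohort,
       truth = list(regionType = regionType, theta = theta,
                    regionBp = regionBp,
                    perPatient = if (is.null(df)) NULL else
                      table(df$patient_id, df$mclass)))
}

#' Write a full simulated dataset to disk
#'
#' Emits exactly the formats the pipeline readers consume: `chrom.sizes`,
#' `genes.gtf`, `peaks.bed`, `expression.tsv`, `drip.bedGraph`,
#' `driprh.bedGraph`, `mutations.tsv`, `cohort.tsv`, plus truth tables
#' (`truth_*.tsv`). All outputs are plain text and byte-stable for a fixed
#' config.
#'
#' @param sim list as returned by [simulateAll()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  writeChromSizes(sim$genome$seqinfo, fp("chrom.sizes"))
  g <- sim$genome$genes
  gtf <- granges(g)
  gtf$source <- "termloop_sim"
  gtf$type <- "gene"
  gtf$gene_id <- g$gene_id
  rtracklayer::export(gtf, fp("genes.gtf"), format = "gtf")
  exportRegions(sim$peaks$peaks, fp("peaks.bed"))
  writeExpression(sim$expression$expression, fp("expression.tsv"))
  rtracklayer::export(sim$signal$drip, fp("drip.bedGraph"),
                      format = "bedGraph")
  rtracklayer::export(sim$signal$dripRH, fp("driprh.bedGraph"),
                      format = "bedGraph")
  writeMutationCatalog(sim$mutations$mutations, fp("mutations.tsv"))
  writeCohort(sim$mutations$cohort, fp("cohort.tsv"))
  write.table(sim$genome$truth, fp("truth_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$peaks$truth, fp("truth_peaks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$expression$truth, fp("truth_expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$signal$truth, fp("truth_signal.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate every pipeline input in one call
#'
#' Chains the generators: genome, peaks, expression (TR genes = genes whose
#' TR received a planted peak), DRIP signal over the planted TR peak
#' intervals, and mutation catalogs with the configured rate ratios over
#' the TR genes' regions.
#'
#' @param config a [SimulationConfig-class].
#' @param mutationRegionType region definition carrying the planted
#'   mutation effect.
#' @return a named list with components `genome`, `peaks`, `trGeneIds`,
#'   `expression`, `signal`, `mutations`.
#' @export
simulateAll <- function(config,
                        mutationRegionType = c("tts_window", "whole_gene")) {
  mutationRegionType <- match.arg(mutationRegionType)
  genome <- simulateGenome(config)
  peaks <- simulatePeaks(config, genome$genes)
  trGeneIds <- sort(unique(stats::na.omit(peaks$truth$target_gene)))
  expression <- simulateExpression(config, genome$genes$gene_id, trGeneIds)
  trPeaks <- peaks$peaks[peaks$peaks$in_tr]
  signal <- simulateSignal(config, trPeaks)
  mutations <- simulateMutations(config, genome$genes, trGeneIds,
                                 regionType = mutationRegionType)
  list(genome = genome, peaks = peaks, trGeneIds = trGeneIds,
       expression = expression, signal = signal, mutations = mutations)
}
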