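#' Read gene models
#'
#' Parses GTF/GFF3 or BED(12) annotations into one gene model per gene: a
#' `GRanges` spanning the transcript body, with `gene_id` metadata. The
#' transcription start site (TSS) is the 5' end of the span in transcription
#' direction and the transcription termination site (TTS) the 3' end; see
#' [geneTSS()]/[geneTTS()].
#'
#' For GTF/GFF3, `gene`-typed records are used when present; otherwise
#' transcript records are collapsed per `gene_id`, taking the transcript with
#' the most extreme annotated 3' end (one TTS per gene). Records with unknown
#' strand are skipped with a warning, since TSS/TTS are undefined for them.
#'
#' @param path annotation file.
#' @param format "auto" (by extension), "gtf", "gff3" or "bed".
#' @param genome optional genome (Seqinfo, named length vector or chrom.sizes
#'   path); attaches sequence lengths used later for clipping.
#' @return a `GRanges` of gene spans, named by `gene_id`, sorted by position.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1\tsrc\tgene\t1001\t2000\t.\t+\t.",
#'                  "gene_id \"g1\";"), gtf)
#' readGeneModels(gtf)
#' @export
readGeneModels <- function(path, format = c("auto", "gtf", "gff3", "bed"),
                           genome = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf"
      else if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3"
      else if (grepl("\\.bed(12)?(\\.gz)?$", path, ignore.case = TRUE)) "bed"
      else stop("cannot infer annotation format from extension: ", path)
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "bed" else format),
    error = function(e) stop("malformed ", format, " file '", path, "': ",
                             conditionMessage(e)))
  if (format == "bed") {
    if (is.null(gr$name)) stop("BED gene models require a name column")
    gr$gene_id <- gr$name
    genes <- granges(gr)
    genes$gene_id <- gr$gene_id
  } else {
    type <- as.character(gr$type)
    if (any(type == "gene")) {
      gr <- gr[type == "gene"]
    } else if (any(type == "transcript" | type == "mRNA")) {
      gr <- gr[type %in% c("transcript", "mRNA")]
    }
    if (is.null(gr$gene_id) || anyNA(gr$gene_id))
      stop("annotation records lack a gene_id attribute")
    genes <- granges(gr)
    genes$gene_id <- as.character(gr$gene_id)
  }
  unknown <- as.character(strand(genes)) == "*"
  if (any(unknown)) {
    warning(sum(unknown), " record(s) with unknown strand skipped")
    genes <- genes[!unknown]
  }
  if (anyDuplicated(genes$gene_id)) {
    # one model per gene: the transcript reaching the most extreme 3' end
    keep <- unlist(lapply(split(seq_along(genes), genes$gene_id), function(i) {
      g <- genes[i]
      if (as.character(strand(g))[1] == "+") i[which.max(end(g))]
      else i[which.min(start(g))]
    }), use.names = FALSE)
    genes <- genes[sort(keep)]
  }
  names(genes) <- genes$gene_id
  if (!is.null(genome)) {
    si <- .asSeqinfo(genome)
    .checkChromsCovered(genes, si, "gene models")
    seqlevels(genes) <- seqlevels(si)
    seqinfo(genes) <- si
  }
  sort(genes, ignore.strand = TRUE)
}

#' TSS and TTS positions of gene models
#'
#' The TSS is the first transcribed base (start on `+`, end on `-`); the TTS
#' is the last transcribed base (end on `+`, start on `-`), both 1-based.
#'
#' @param genes gene models from [readGeneModels()].
#' @return named integer vector of positions.
#' @export
geneTSS <- function(genes) {
  .checkStranded(genes)
  setNames(ifelse(strand(genes) == "+", start(genes), end(genes)),
           genes$gene_id)
}

#' @rdname geneTSS
#' @export
geneTTS <- function(genes) {
  .checkStranded(genes)
  setNames(ifelse(strand(genes) == "+", end(genes), start(genes)),
           genes$gene_id)
}

.checkStranded <- function(genes) {
  if (any(strand(genes) == "*"))
    stop("gene models must be stranded (+ or -)")
  if (is.null(genes$gene_id)) stop("gene models must carry a gene_id column")
  invisible(TRUE)
}

.regionSet <- function(genes, start, end, name, genome) {
  # built without seqinfo so transiently out-of-bound regions do not warn
  # twice; .clipToGenome attaches the seqinfo after clipping
  out <- GRanges(as.character(seqnames(genes)), IRanges(start, end),
                 strand = as.character(strand(genes)),
                 gene_id = genes$gene_id)
  names(out) <- genes$gene_id
  S4Vectors::metadata(out)$regionType <- name
  .clipToGenome(out, if (is.null(genome)) seqinfo(genes) else genome)
}

#' Construct termination regions (TRs)
#'
#' The TR of a gene is the `length`-bp segment immediately downstream of its
#' TTS in the direction of transcription: bases `TTS+1 .. TTS+length` on the
#' `+` strand and `TTS-length .. TTS-1` on the `-` strand. Regions running
#' off a chromosome end are clipped with a warning.
#'
#' @param genes stranded gene models with `gene_id`.
#' @param length region length in bp (default 4000, the canonical TR width).
#' @param genome optional genome used for clipping (defaults to the
#'   seqlengths carried by `genes`).
#' @return `GRanges` of one region per gene, named by `gene_id`.
#' @seealso [wholeGeneRegions()], [ttsWindows()], [promoterRegions()]
#' @export
terminationRegions <- function(genes, length = 4000, genome = NULL) {
  .checkStranded(genes)
  if (length <= 0) stop("'length' must be a positive number of bases")
  plus <- strand(genes) == "+"
  s <- ifelse(plus, end(genes) + 1L, start(genes) - length)
  e <- ifelse(plus, end(genes) + length, start(genes) - 1L)
  .regionSet(genes, s, e, "termination_region", genome)
}

#' Construct whole-gene regions of interest
#'
#' Strand-aware extension of the transcript span: from `upstream` bp before
#' the TSS to `downstream` bp past the TTS in transcription direction
#' (defaults 1250 and 5000).
#'
#' @inheritParams terminationRegions
#' @param upstream bp added upstream of the TSS.
#' @param downstream bp added downstream of the TTS.
#' @export
wholeGeneRegions <- function(genes, upstream = 1250, downstream = 5000,
                             genome = NULL) {
  .checkStranded(genes)
  if (upstream < 0 || downstream < 0)
    stop("'upstream' and 'downstream' must be >= 0")
  plus <- strand(genes) == "+"
  s <- ifelse(plus, start(genes) - upstream, start(genes) - downstream)
  e <- ifelse(plus, end(genes) + downstream, end(genes) + upstream)
  .regionSet(genes, s, e, "whole_gene", genome)
}

#' Construct symmetric TTS windows
#'
#' A window of `2 * flank` bp centred on the TTS boundary (the junction
#' between the last transcribed base and the first downstream base), i.e.
#' `flank` bp of gene body plus `flank` bp of downstream sequence on either
#' strand.
#'
#' @inheritParams terminationRegions
#' @param flank half-width in bp (default 4000, giving TTS +/- 4 kb).
#' @export
ttsWindows <- function(genes, flank = 4000, genome = NULL) {
  .checkStranded(genes)
  if (flank <= 0) stop("'flank' must be > 0 (empty window)")
  plus <- strand(genes) == "+"
  s <- ifelse(plus, end(genes) - flank + 1L, start(genes) - flank)
  e <- ifelse(plus, end(genes) + flank, start(genes) + flank - 1L)
  .regionSet(genes, s, e, "tts_window", genome)
}

#' Construct promoter regions
#'
#' Strand-aware window around the TSS, by default the 1250 bp immediately
#' upstream (ending at the base before the TSS). Used to exclude
#' promoter-bound peaks from TR overlap analyses.
#'
#' @inheritParams terminationRegions
#' @param upstream bp upstream of the TSS.
#' @param downstream bp downstream of (and including) the TSS.
#' @export
promoterRegions <- function(genes, upstream = 1250, downstream = 0,
                            genome = NULL) {
  .checkStranded(genes)
  if (upstream + downstream <= 0)
    stop("empty promoter window: upstream + downstream must be > 0")
  plus <- strand(genes) == "+"
  s <- ifelse(plus, start(genes) - upstream, end(genes) - downstream + 1L)
  e <- ifelse(plus, start(genes) + downstream - 1L, end(genes) + upstream)
  .regionSet(genes, s, e, "promoter", genome)
}
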