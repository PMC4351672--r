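#' Read and write chromosome sizes
#'
#' Two-column, tab-separated `chrom<TAB>length` files (UCSC chrom.sizes
#' convention), represented in R as a [GenomeInfoDb::Seqinfo].
#'
#' @param path file path.
#' @return `readChromSizes` returns a `Seqinfo`; `writeChromSizes` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".sizes")
#' writeChromSizes(GenomeInfoDb::Seqinfo("chr1", 1e6), f)
#' readChromSizes(f)
#' @export
readChromSizes <- function(path) {
  tab <- read.delim(path, header = FALSE, col.names = c("chrom", "length"),
                    colClasses = c("character", "integer"))
  if (nrow(tab) == 0L) stop("empty chrom.sizes file: ", path)
  Seqinfo(seqnames = tab$chrom, seqlengths = tab$length)
}

#' @param si a `Seqinfo` or named vector of chromosome lengths.
#' @rdname readChromSizes
#' @export
writeChromSizes <- function(si, path) {
  si <- .asSeqinfo(si)
  write.table(data.frame(GenomeInfoDb::seqnames(si), seqlengths(si)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a ChIP-seq peak set
#'
#' Accepts BED3+ and ENCODE narrowPeak; extra columns beyond the interval,
#' name and strand are kept as metadata but ignored by all overlap logic.
#' Peaks are returned sorted by (chromosome, start).
#'
#' @param path BED or narrowPeak file.
#' @param name label for the peak set (e.g. "BRCA1"), stored in
#'   `metadata(x)$name`.
#' @param genome optional genome (Seqinfo, named length vector, or
#'   chrom.sizes path); when given, peaks are checked against it.
#' @return a sorted [GenomicRanges::GRanges]; unnamed peaks are given
#'   names `peak_1 ...` in file order.
#' @export
readPeaks <- function(path, name = basename(path), genome = NULL) {
  if (grepl("\\.narrowPeak$", path, ignore.case = TRUE)) {
    extra <- c(signalValue = "numeric", pValue = "numeric",
               qValue = "numeric", peak = "integer")
    gr <- rtracklayer::import(path, format = "bed", extraCols = extra)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
  }
  if (is.null(gr$name) || anyNA(gr$name) || anyDuplicated(gr$name)) {
    gr$name <- sprintf("peak_%d", seq_along(gr))
  }
  names(gr) <- gr$name
  gr <- sort(gr, ignore.strand = TRUE)
  if (!is.null(genome)) {
    si <- .asSeqinfo(genome)
    .checkChromsCovered(gr, si, "peaks")
    seqlevels(gr) <- seqlevels(si)
    seqinfo(gr) <- si
  }
  S4Vectors::metadata(gr)$name <- name
  gr
}

#' Write a region or peak set as BED6
#'
#' Emits `chrom start end name score strand` with BED's 0-based half-open
#' coordinates (conversion handled by rtracklayer); names default to the
#' `gene_id` metadata column when present.
#'
#' @param gr a `GRanges`.
#' @param path output file.
#' @export
exportRegions <- function(gr, path) {
  if (is.null(gr$name)) {
    gr$name <- if (!is.null(gr$gene_id)) gr$gene_id
               else if (!is.null(names(gr))) names(gr)
               else sprintf("region_%d", seq_along(gr))
  }
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read and write gene expression tables
#'
#' Two-column tab-separated files with a header (`gene_id`, `value`);
#' values are RPKM-like, finite and non-negative.
#'
#' @param path file path.
#' @return `readExpression` returns a named numeric vector.
#' @export
readExpression <- function(path) {
  tab <- read.delim(path, header = TRUE, colClasses = c("character", "numeric"))
  x <- tab[[2]]
  names(x) <- tab[[1]]
  if (any(!is.finite(x)) || any(x < 0))
    stop("expression values must be finite and >= 0")
  if (anyDuplicated(names(x)))
    stop("duplicate gene_id in expression table")
  x
}

#' @param x named numeric vector of expression values.
#' @param units free-text units label written as a comment-free header name.
#' @rdname readExpression
#' @export
writeExpression <- function(x, path, units = "RPKM") {
  df <- data.frame(gene_id = names(x), value = as.numeric(x))
  names(df)[2] <- units
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file; intervals must not overlap within a chromosome.
#' @return a `GRanges` with a numeric `score` column (signal per base).
#' @export
readBedGraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(gr$score < 0)) stop("coverage values must be non-negative")
  red <- reduce(gr, ignore.strand = TRUE)
  if (sum(width(red)) != sum(width(gr)))
    stop("bedGraph intervals overlap within a chromosome")
  gr
}

.MUTATION_CLASSES <- c("SBM", "indel", "rearrangement")

#' Read a somatic mutation catalog
#'
#' Mutations are represented as width-1 `GRanges` (for indels the first
#' affected base; for rearrangements each breakpoint is one record) with
#' metadata columns `patient_id`, `mclass` (one of `SBM`, `indel`,
#' `rearrangement`), and optional `ref`/`alt`.
#'
#' Two formats are supported. A consolidated TSV with header columns
#' `patient_id, chrom, pos, mclass[, ref, alt]` (1-based positions) may mix
#' patients and classes; rearrangement breakpoints are only representable
#' here. A per-patient VCF is classified from its alleles: equal-length
#' single-base substitution = `SBM`, length-changing allele = `indel`.
#'
#' @param path input file.
#' @param format "auto" (by extension), "tsv" or "vcf".
#' @param patient patient identifier, required for VCF input.
#' @return `GRanges` of mutation records.
#' @seealso [subtractGermline()], [countRegionHits()]
#' @export
readMutationCatalog <- function(path, format = c("auto", "tsv", "vcf"),
                                patient = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
              else "tsv"
  if (format == "tsv") {
    tab <- read.delim(path, header = TRUE, colClasses = "character")
    need <- c("patient_id", "chrom", "pos", "mclass")
    if (!all(need %in% names(tab)))
      stop("mutation TSV must have columns: ", paste(need, collapse = ", "))
    bad <- which(!tab$mclass %in% .MUTATION_CLASSES)
    if (length(bad))
      stop("unknown mutation class '", tab$mclass[bad[1]], "' at line ",
           bad[1] + 1L, " of ", path)
    gr <- GRanges(tab$chrom, IRanges(as.integer(tab$pos), width = 1L),
                  patient_id = tab$patient_id,
                  mclass = tab$mclass,
                  ref = if ("ref" %in% names(tab)) tab$ref else NA_character_,
                  alt = if ("alt" %in% names(tab)) tab$alt else NA_character_)
  } else {
    if (is.null(patient))
      stop("'patient' is required when reading a per-patient VCF")
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    refs <- as.character(VariantAnnotation::ref(vcf))
    alts <- vapply(VariantAnnotation::alt(vcf),
                   function(a) as.character(a)[1], character(1))
    mclass <- ifelse(nchar(refs) == 1L & nchar(alts) == 1L, "SBM", "indel")
    gr <- GRanges(seqnames(rr), IRanges(start(rr), width = 1L),
                  patient_id = patient, mclass = mclass,
                  ref = refs, alt = alts)
  }
  names(gr) <- NULL
  sort(gr, ignore.strand = TRUE)
}

#' @param records mutation `GRanges` as returned by [readMutationCatalog()].
#' @rdname readMutationCatalog
#' @export
writeMutationCatalog <- function(records, path) {
  df <- data.frame(patient_id = records$patient_id,
                   chrom = as.character(seqnames(records)),
                   pos = start(records),
                   mclass = as.character(records$mclass),
                   ref = records$ref, alt = records$alt)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write cohort group assignments
#'
#' Tab-separated `patient_id, group` with header; each patient belongs to
#' exactly one group.
#'
#' @param path file path.
#' @return `readCohort` returns a named character vector mapping
#'   `patient_id` to group.
#' @export
readCohort <- function(path) {
  tab <- read.delim(path, header = TRUE, colClasses = "character")
  if (!all(c("patient_id", "group") %in% names(tab)))
    stop("cohort table must have columns patient_id and group")
  if (anyDuplicated(tab$patient_id))
    stop("each patient must appear in exactly one group")
  setNames(tab$group, tab$patient_id)
}

#' @param cohort named character vector (names = patients, values = groups).
#' @rdname readCohort
#' @export
writeCohort <- function(cohort, path) {
  write.table(data.frame(patient_id = names(cohort), group = unname(cohort)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
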