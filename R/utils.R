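# internal helpers shared across modules

# Coerce a genome description (Seqinfo, named length vector, or chrom.sizes
# file path) to a Seqinfo.
.asSeqinfo <- function(genome) {
  if (is(genome, "Seqinfo")) return(genome)
  if (is.numeric(genome) && !is.null(names(genome)))
    return(Seqinfo(seqnames = names(genome), seqlengths = as.integer(genome)))
  if (is.character(genome) && length(genome) == 1L)
    return(readChromSizes(genome))
  stop("'genome' must be a Seqinfo, a named vector of chromosome lengths, ",
       "or a chrom.sizes file path")
}

# Attach seqlengths and clip ranges to [1, chrom length], warning when any
# range is altered; zero-width survivors are dropped. Genes near a chromosome
# edge keep a (shortened) region rather than vanishing, so enrichment
# denominators are preserved.
.clipToGenome <- function(gr, genome = NULL) {
  si <- if (!is.null(genome)) .asSeqinfo(genome) else seqinfo(gr)
  lens <- seqlengths(si)[as.character(seqnames(gr))]
  newStart <- pmax(start(gr), 1L)
  newEnd <- ifelse(is.na(lens), end(gr), pmin(end(gr), lens))
  clipped <- newStart != start(gr) | newEnd != end(gr)
  empty <- newStart > newEnd
  if (any(clipped))
    warning(sum(clipped), " region(s) clipped to chromosome bounds")
  nm <- names(gr)
  ranges(gr) <- IRanges(pmin(newStart, newEnd), newEnd)
  names(gr) <- nm
  if (!is.null(genome)) {
    seqlevels(gr) <- seqlevels(si)
    seqinfo(gr) <- si
  }
  if (any(empty)) {
    warning(sum(empty), " region(s) fell entirely outside the chromosome ",
            "and were dropped")
    gr <- gr[!empty]
  }
  gr
}

.checkChromsCovered <- function(gr, si, what = "ranges") {
  miss <- setdiff(as.character(unique(seqnames(gr))), seqnames(si))
  if (length(miss))
    stop("chromosome(s) present in ", what,
         " but absent from the genome table: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

# Upper tail P(S >= k) of a sum of independent Bernoulli(p_j) variables,
# by the standard convolution recursion. Exact up to floating point.
.poisbinomTail <- function(p, k) {
  if (k <= 0) return(1)
  if (k > length(p)) return(0)
  f <- 1
  for (pj in p) f <- c(f * (1 - pj), 0) + c(0, f * pj)
  max(sum(f[(k + 1):length(f)]), 1e-300)
}
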