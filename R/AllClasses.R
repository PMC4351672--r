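#' Result of a peak-region overlap count or enrichment test
#'
#' Container for the observed number of distinct peaks overlapping at least
#' one region, the expected count under the uniform-placement null, the
#' upper-tail p value, and the individual (peak, gene) overlap pairs.
#'
#' @slot observed integer, number of distinct peaks overlapping >= 1 region.
#' @slot nPeaks integer, total number of peaks tested.
#' @slot lambda numeric, expected overlap count under the uniform-placement
#'   null (`NA` when no null was evaluated).
#' @slot pValue numeric, upper-tail probability of observing at least
#'   `observed` overlapping peaks under the null (`NA` when not evaluated).
#' @slot method character, tail computation used ("exact" Poisson-binomial
#'   or "poisson").
#' @slot pairs [S4Vectors::DataFrame] of (peak, gene_id) overlap pairs.
#'
#' @seealso [countOverlappingPeaks()], [poissonOverlapTest()]
#' @exportClass OverlapResult
setClass("OverlapResult",
  representation(
    observed = "integer",
    nPeaks   = "integer",
    lambda   = "numeric",
    pValue   = "numeric",
    method   = "character",
    pairs    = "DataFrame"
  )
)

setValidity("OverlapResult", function(object) {
  msg <- NULL
  if (object@observed < 0L || object@observed > object@nPeaks)
    msg <- c(msg, "'observed' must lie in [0, nPeaks]")
  if (!is.na(object@lambda) && object@lambda < 0)
    msg <- c(msg, "'lambda' must be >= 0")
  if (!is.na(object@pValue) && (object@pValue <= 0 || object@pValue > 1))
    msg <- c(msg, "'pValue' must lie in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Result of a chromosome-aware peak shuffle null
#'
#' @slot observedFraction numeric, fraction of peaks overlapping a region.
#' @slot nullFractions numeric vector, one overlap fraction per shuffle.
#' @slot empiricalP numeric, add-one empirical p value
#'   `(1 + #\{null >= observed\}) / (nShuffles + 1)`.
#' @slot foldEnrichment numeric, `observedFraction / mean(nullFractions)`.
#' @slot nShuffles integer. @slot seed integer, RNG seed used.
#'
#' @seealso [shuffleEnrichment()]
#' @exportClass ShuffleResult
setClass("ShuffleResult",
  representation(
    observedFraction = "numeric",
    nullFractions    = "numeric",
    empiricalP       = "numeric",
    foldEnrichment   = "numeric",
    nShuffles        = "integer",
    seed             = "integer"
  )
)

setValidity("ShuffleResult", function(object) {
  msg <- NULL
  if (length(object@nullFractions) != object@nShuffles)
    msg <- c(msg, "'nullFractions' must have one entry per shuffle")
  if (object@empiricalP < 1 / (object@nShuffles + 1) - 1e-12)
    msg <- c(msg, "'empiricalP' must be >= 1/(nShuffles+1)")
  if (!is.na(object@foldEnrichment) && object@foldEnrichment < 0)
    msg <- c(msg, "'foldEnrichment' must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Stratified Cochran-Mantel-Haenszel Z result
#'
#' One-tailed CMH effect size for regional mutation hits, stratified by gene:
#' `Z = sum_k(a_k - E_k) / sqrt(sum_k V_k)` with `a_k` the number of group-A
#' patients with a hit in gene k's region, `E_k = n_A m_k / N` and
#' `V_k = n_A n_B m_k (N - m_k) / (N^2 (N - 1))`. Positive Z means
#' enrichment in group A; `p = 1 - pnorm(Z)`.
#'
#' @slot z numeric, the standardized effect size (`NA` when degenerate).
#' @slot p numeric, one-tailed p value.
#' @slot strata [S4Vectors::DataFrame] of per-gene `a`, `m`, `E`, `V`.
#' @slot groups character of length 2, `c(groupA, groupB)`.
#' @slot variant character, "binary" (patient has >= 1 hit) or "count".
#' @slot degenerate logical, `TRUE` when the total variance is zero and no
#'   comparison is possible.
#'
#' @seealso [cmhZ()], [effectSizePanel()]
#' @exportClass CMHResult
setClass("CMHResult",
  representation(
    z          = "numeric",
    p          = "numeric",
    strata     = "DataFrame",
    groups     = "character",
    variant    = "character",
    degenerate = "logical"
  )
)

setValidity("CMHResult", function(object) {
  msg <- NULL
  if (!object@degenerate && !is.finite(object@z))
    msg <- c(msg, "'z' must be finite unless the result is degenerate")
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    msg <- c(msg, "'p' must lie in [0, 1]")
  if (length(object@groups) != 2L)
    msg <- c(msg, "'groups' must name the two compared groups")
  if (is.null(msg)) TRUE else msg
})

#' Parameters of the synthetic-data generators
#'
#' A single object stating the simulated world: genome layout, peak
#' placement, expression model, DRIP-type signal and per-patient mutation
#' process. Defaults are desk-scale (one 10 Mb chromosome, 200 genes,
#' 500 peaks, 21 patients) so every closed-loop simulation completes in
#' seconds; see the package vignette for the rationale behind each value.
#'
#' @slot seed integer, master seed; each generator derives its own stream.
#' @slot nChroms,chromLength integer/numeric, genome layout.
#' @slot nGenes integer; @slot geneLengthRange numeric length-2 (bp, uniform);
#'   @slot minFlank numeric, minimum gap between genes (bp).
#' @slot nPeaks integer; @slot fracPeaksInTR numeric in `[0,1]`, fraction of
#'   peaks planted inside termination regions; @slot peakLengthRange numeric
#'   length-2 (bp, uniform).
#' @slot exprMeanlog,exprSdlog numeric, log-normal expression parameters;
#'   @slot trBoost numeric, multiplicative expression boost for TR genes;
#'   @slot silentFraction numeric, fraction of non-TR genes set to zero.
#' @slot signalMean numeric, mean DRIP count per region;
#'   @slot rhFactor numeric in `[0,1]`, RNaseH depletion factor applied to
#'   the DRIP+RH track; @slot backgroundSignal numeric, mean background count
#'   per kb outside the signal regions.
#' @slot cohortSizes named integer (sporadic, BRCA1, BRCA2 group sizes).
#' @slot mutationRates named numeric, per-patient mutation rate per Mb for
#'   classes SBM, indel, rearrangement.
#' @slot theta named list of named numerics,
#'   `theta[[group]][[class]]` = rate ratio applied within the designated
#'   regions of TR genes for patients of that group (1 = no enrichment).
#'
#' @seealso [simulationConfig()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    seed            = "integer",
    nChroms         = "integer",
    chromLength     = "numeric",
    nGenes          = "integer",
    geneLengthRange = "numeric",
    minFlank        = "numeric",
    nPeaks          = "integer",
    fracPeaksInTR   = "numeric",
    peakLengthRange = "numeric",
    exprMeanlog     = "numeric",
    exprSdlog       = "numeric",
    trBoost         = "numeric",
    silentFraction  = "numeric",
    signalMean      = "numeric",
    rhFactor        = "numeric",
    backgroundSignal = "numeric",
    cohortSizes     = "integer",
    mutationRates   = "numeric",
    theta           = "list"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  inunit <- function(x) all(x >= 0 & x <= 1)
  if (!inunit(object@fracPeaksInTR)) msg <- c(msg, "'fracPeaksInTR' must lie in [0,1]")
  if (!inunit(object@silentFraction)) msg <- c(msg, "'silentFraction' must lie in [0,1]")
  if (!inunit(object@rhFactor)) msg <- c(msg, "'rhFactor' must lie in [0,1]")
  if (any(object@mutationRates < 0)) msg <- c(msg, "mutation rates must be >= 0")
  if (!all(c("SBM", "indel", "rearrangement") %in% names(object@mutationRates)))
    msg <- c(msg, "'mutationRates' must name SBM, indel and rearrangement")
  if (!all(c("sporadic", "BRCA1", "BRCA2") %in% names(object@cohortSizes)))
    msg <- c(msg, "'cohortSizes' must name sporadic, BRCA1 and BRCA2")
  if (any(object@geneLengthRange <= 0) || diff(object@geneLengthRange) < 0)
    msg <- c(msg, "'geneLengthRange' must be increasing and positive")
  th <- unlist(object@theta)
  if (length(th) && any(th < 0)) msg <- c(msg, "theta rate ratios must be >= 0")
  if (is.null(msg)) TRUE else msg
})

## ---- show methods -------------------------------------------------------

setMethod("show", "OverlapResult", function(object) {
  cat("OverlapResult:", object@observed, "of", object@nPeaks,
      "peaks overlap >= 1 region\n")
  if (!is.na(object@lambda))
    cat("  expected (lambda):", format(object@lambda, digits = 4),
        " p (", object@method, "): ", format(object@pValue, digits = 4),
        "\n", sep = "")
  cat("  overlap pairs:", nrow(object@pairs),
      "(", length(unique(object@pairs$gene_id)), "unique genes )\n")
})

setMethod("show", "ShuffleResult", function(object) {
  cat("ShuffleResult:", object@nShuffles, "shuffles (seed ", object@seed, ")\n")
  cat("  observed fraction:", format(object@observedFraction, digits = 4),
      " fold enrichment:", format(object@foldEnrichment, digits = 4),
      " empirical p:", format(object@empiricalP, digits = 4), "\n")
})

setMethod("show", "CMHResult", function(object) {
  cat("CMHResult (", object@variant, "): ", object@groups[1], " vs ",
      object@groups[2], "\n", sep = "")
  if (object@degenerate) {
    cat("  degenerate: no informative strata (p = 1)\n")
  } else {
    cat("  Z =", format(object@z, digits = 4),
        " one-tailed p =", format(object@p, digits = 4),
        " informative strata:", nrow(object@strata), "\n")
  }
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig (seed ", object@seed, ")\n", sep = "")
  cat("  genome: ", object@nChroms, " x ", format(object@chromLength, big.mark = ","),
      " bp, ", object@nGenes, " genes\n", sep = "")
  cat("  peaks: ", object@nPeaks, " (fraction in TR: ", object@fracPeaksInTR,
      ")\n", sep = "")
  cat("  cohort:", paste(names(object@cohortSizes), object@cohortSizes,
                         sep = "=", collapse = ", "), "\n")
})

## ---- accessors ----------------------------------------------------------

#' @describeIn OverlapResult-class observed overlap count
#' @param x an `OverlapResult`
#' @export
observedOverlaps <- function(x) x@observed

#' @describeIn OverlapResult-class expected overlap count under the null
#' @export
expectedOverlaps <- function(x) x@lambda

#' @describeIn OverlapResult-class upper-tail p value
#' @export
overlapPValue <- function(x) x@pValue

#' @describeIn OverlapResult-class DataFrame of (peak, gene_id) pairs
#' @export
overlapPairs <- function(x) x@pairs

#' @describeIn ShuffleResult-class per-shuffle null overlap fractions
#' @param x a `ShuffleResult`
#' @export
nullFractions <- function(x) x@nullFractions

#' @describeIn ShuffleResult-class add-one empirical p value
#' @export
empiricalP <- function(x) x@empiricalP

#' @describeIn ShuffleResult-class observed/expected overlap fraction ratio
#' @export
foldEnrichment <- function(x) x@foldEnrichment

#' @describeIn CMHResult-class the standardized Z effect size
#' @param x a `CMHResult`
#' @export
cmhStatistic <- function(x) x@z

#' @describeIn CMHResult-class the one-tailed p value
#' @export
cmhPValue <- function(x) x@p

#' @describeIn CMHResult-class per-stratum contributions (a, m, E, V)
#' @export
cmhStrata <- function(x) x@strata
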