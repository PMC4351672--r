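#' Classify expressed genes
#'
#' @param expression named numeric vector of RPKM-like values.
#' @param threshold minimum value to call a gene expressed (default 1.0;
#'   conventional, as no universal cutoff exists).
#' @return character vector of expressed gene ids.
#' @export
classifyExpressed <- function(expression, threshold = 1.0) {
  if (any(!is.finite(expression)) || any(expression < 0))
    stop("expression values must be finite and >= 0")
  names(expression)[expression >= threshold]
}

#' Compare expression between two gene groups (Mann-Whitney U)
#'
#' Rank-based comparison of expression values, e.g. TR-bound vs unbound
#' genes. The default alternative is one-sided "greater" (group A more
#' highly expressed), matching the directional claim such comparisons are
#' used for; two-sided is available. Exact enumeration is used when both
#' groups have at most 20 untied values, otherwise the tie-corrected normal
#' approximation.
#'
#' @param groupA,groupB numeric vectors of expression values (non-empty).
#' @param alternative "greater" (default) or "two.sided".
#' @return a list with elements `statistic` (the U statistic for group A),
#'   `p.value`, `alternative` and `method`.
#' @export
compareExpression <- function(groupA, groupB,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!length(groupA) || !length(groupB))
    stop("both groups must be non-empty")
  pooled <- c(groupA, groupB)
  if (length(unique(pooled)) == 1L) {
    warning("all values tied across both groups; p = 1")
    return(list(statistic = length(groupA) * length(groupB) / 2,
                p.value = 1, alternative = alternative,
                method = "Mann-Whitney U (degenerate)"))
  }
  exact <- length(groupA) <= 20 && length(groupB) <= 20
  ht <- suppressWarnings(
    wilcox.test(groupA, groupB, alternative = alternative, exact = exact,
                correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       alternative = alternative, method = ht$method)
}
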