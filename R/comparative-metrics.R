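# Host-vs-target comparison of %MinMax profiles, plus CAI and GC content.

# Both comparison parameters require profiles of the same CDS under two
# tables: same window size, same window grid.
.checkComparable <- function(pHost, pTarget) {
  if (pHost@windowSize != pTarget@windowSize)
    .alignmentError(sprintf(
      "window sizes differ (%d vs %d)", pHost@windowSize,
      pTarget@windowSize))
  if (length(pHost@values) != length(pTarget@values) ||
      !identical(pHost@windowStart, pTarget@windowStart))
    .alignmentError(sprintf(
      "profiles are not aligned: %d vs %d windows",
      length(pHost@values), length(pTarget@values)))
  invisible(TRUE)
}

#' Mean absolute difference between two %MinMax profiles
#'
#' The host/target comparison parameter sensitive to the absolute level of
#' the two codon-cluster landscapes: the mean over all n windows of
#' |x_i - y_i|, where x is the profile under one table and y under the
#' other. Units are percentage points; 0 means identical profiles.
#'
#' @param pHost,pTarget [MinMaxProfile-class] objects for the same CDS and
#'   window size, computed under two usage tables.
#' @return non-negative number.
#' @seealso [minMaxCorrelation()], [compareProfiles()]
#' @export
deltaMinMax <- function(pHost, pTarget) {
  .checkComparable(pHost, pTarget)
  mean(abs(pHost@values - pTarget@values))
}

#' Correlation between two %MinMax profiles
#'
#' The host/target comparison parameter sensitive to the shape of the two
#' landscapes regardless of their absolute offset: the Pearson correlation
#' over windows, with the host-table profile as x and the target-table
#' profile as y. A constant profile (e.g. an all-most-frequent-codon
#' recoded gene, flat at +100) makes the correlation undefined; this is
#' reported as an explicit undefined [CorrelationResult-class], never a
#' silent NaN.
#'
#' @inheritParams deltaMinMax
#' @return a [CorrelationResult-class] with n = number of windows.
#' @export
minMaxCorrelation <- function(pHost, pTarget) {
  .checkComparable(pHost, pTarget)
  pearsonWithP(pHost@values, pTarget@values)
}

#' Codon adaptation index
#'
#' CAI = exp(mean over the gene's L sense codons of ln w), the geometric
#' mean of the relative adaptiveness values under a reference table
#' (typically built from highly expressed genes of the host). A gene using
#' only each family's most frequent codon scores 1.
#'
#' @param cds DNA coding sequence (trailing stop stripped; internal stops
#'   are errors).
#' @param table reference [CodonUsageTable-class].
#' @param trim5 codons to discard from the 5' end first (default 0).
#' @return CAI in (0, 1].
#' @seealso [relativeAdaptiveness()]
#' @export
cai <- function(cds, table, trim5 = 0L) {
  cods <- .cdsCodons(cds, table@code)
  if (trim5 > 0L) {
    if (trim5 >= length(cods))
      .tooShortError(sprintf("trim5 = %d leaves no codons", trim5))
    cods <- cods[-seq_len(trim5)]
  }
  w <- relativeAdaptiveness(table)
  exp(mean(log(w[cods])))
}

#' GC content of a sequence
#'
#' @param cds non-empty A/C/G/T string (U accepted as T).
#' @return fraction of G+C in [0, 1].
#' @export
gcContent <- function(cds) {
  s <- gsub("U", "T", toupper(as.character(cds)[1L]))
  if (nchar(s) == 0L) .domainError("empty sequence")
  if (grepl("[^ACGT]", s)) .alphabetError("non-ACGT character in sequence")
  b <- strsplit(s, "")[[1]]
  sum(b == "G" | b == "C") / length(b)
}

#' ProfileComparison: the full host-vs-target comparison for one ORF
#'
#' Bundles the two comparison parameters (and, when a secondary-structure
#' annotation is supplied, the per-class correlations) for one CDS profiled
#' under a host and a target usage table.
#'
#' @slot orfId,hostOrganism,targetOrganism labels.
#' @slot deltaMinMax mean absolute profile difference (>= 0).
#' @slot correlation overall [CorrelationResult-class].
#' @slot nWindows number of windows compared.
#' @slot perClass named list of [CorrelationResult-class], one per
#'   secondary-structure class (empty when no annotation was supplied).
#' @seealso [compareProfiles()]
#' @export
setClass("ProfileComparison",
  representation(orfId = "character", hostOrganism = "character",
                 targetOrganism = "character", deltaMinMax = "numeric",
                 correlation = "CorrelationResult", nWindows = "integer",
                 perClass = "list"))

setValidity("ProfileComparison", function(object) {
  if (object@deltaMinMax < 0) "deltaMinMax must be non-negative" else TRUE
})

#' Compare a gene's %MinMax profiles under host and target tables
#'
#' @param pHost,pTarget [MinMaxProfile-class] objects for the same CDS
#'   under the host and the target (native) usage table.
#' @param ann optional [SSAnnotation-class]; when given, per-class
#'   correlations are included.
#' @param rule window-to-class assignment rule, `"center"` or
#'   `"majority"` (see [assignWindowClasses()]).
#' @return a [ProfileComparison-class].
#' @export
compareProfiles <- function(pHost, pTarget, ann = NULL,
                            rule = c("center", "majority")) {
  rule <- match.arg(rule)
  .checkComparable(pHost, pTarget)
  perClass <- if (!is.null(ann))
    stratifiedMinMaxCorrelation(pHost, pTarget, ann, rule = rule)
  else list()
  new("ProfileComparison", orfId = pHost@orfId,
      hostOrganism = pHost@organismId, targetOrganism = pTarget@organismId,
      deltaMinMax = deltaMinMax(pHost, pTarget),
      correlation = minMaxCorrelation(pHost, pTarget),
      nWindows = length(pHost@values), perClass = perClass)
}

setMethod("show", "ProfileComparison", function(object) {
  cat(sprintf("ProfileComparison '%s': host %s vs target %s (%d windows)\n",
              object@orfId, object@hostOrganism, object@targetOrganism,
              object@nWindows))
  cat(sprintf("  delta %%MinMax: %.3f\n", object@deltaMinMax))
  cat("  %MinMax Correlation: ")
  show(object@correlation)
  for (cl in names(object@perClass)) {
    cat(sprintf("  class %s: ", cl))
    show(object@perClass[[cl]])
  }
})
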