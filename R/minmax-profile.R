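#' MinMaxProfile: sliding-window rare-codon cluster profile
#'
#' One %MinMax value per window of `windowSize` consecutive codons, sliding
#' one codon at a time. Values live in [-100, 100]: +100 means every codon
#' in the window is its family's most frequent synonym, -100 the rarest,
#' 0 the family average.
#'
#' @slot orfId character label of the profiled CDS.
#' @slot organismId label of the usage table the profile was computed under.
#' @slot windowSize integer window width in codons.
#' @slot values numeric vector of per-window %MinMax values, length
#'   L - windowSize + 1 for a CDS of L sense codons.
#' @slot windowStart integer vector, 0-based codon index of each window's
#'   first codon.
#'
#' @seealso [minMaxProfile()]
#' @export
setClass("MinMaxProfile",
  representation(orfId = "character", organismId = "character",
                 windowSize = "integer", values = "numeric",
                 windowStart = "integer"))

setValidity("MinMaxProfile", function(object) {
  msgs <- character(0)
  if (length(object@values) != length(object@windowStart))
    msgs <- c(msgs, "values and windowStart lengths differ")
  if (any(object@values < -100 - 1e-9 | object@values > 100 + 1e-9))
    msgs <- c(msgs, "%MinMax values must lie in [-100, 100]")
  if (object@windowSize < 1L)
    msgs <- c(msgs, "windowSize must be positive")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn minMaxProfile per-window %MinMax values
#' @param profile a [MinMaxProfile-class].
#' @export
profileValues <- function(profile) profile@values

#' @describeIn minMaxProfile 0-based first-codon index of each window
#' @export
windowStarts <- function(profile) profile@windowStart

#' @describeIn minMaxProfile window width in codons
#' @export
windowSize <- function(profile) profile@windowSize

#' @describeIn minMaxProfile identifier of the profiled CDS
#' @export
orfId <- function(profile) profile@orfId

setMethod("show", "MinMaxProfile", function(object) {
  cat(sprintf("MinMaxProfile '%s' under '%s': %d windows of %d codons\n",
              object@orfId, object@organismId, length(object@values),
              object@windowSize))
  if (length(object@values))
    cat(sprintf("  mean %%MinMax %.2f, range [%.2f, %.2f]\n",
                mean(object@values), min(object@values),
                max(object@values)))
})

# Rolling mean of x over windows of width w, step 1 (exact, via cumsum).
.rollMean <- function(x, w) {
  cs <- cumsum(x)
  (cs[w:length(x)] - c(0, cs)[seq_len(length(x) - w + 1L)]) / w
}

#' Compute the %MinMax profile of a coding sequence
#'
#' For each window of `window` consecutive codons let A be the mean usage
#' frequency of the codons actually present, and Max, Min, Avg the means of
#' the per-codon family maxima, minima and (unweighted) averages. The
#' window's score is
#' \deqn{100 (A - Avg)/(Max - Avg)} when A >= Avg, and
#' \deqn{-100 (Avg - A)/(Avg - Min)} otherwise,
#' i.e. the window's position between the most-common-codon ceiling (+100)
#' and the rarest-codon floor (-100), with 0 at the family average. A
#' window in which every codon's family is uniform (A = Avg = Max = Min,
#' e.g. all-Met) scores 0, the continuous completion of both branches.
#'
#' A trailing stop codon is stripped before profiling; internal stops,
#' non-ACGT characters and out-of-frame lengths are errors. `trim5` drops
#' N codons from the 5' end first (e.g. a His6 tag and protease site that
#' are not part of the native gene).
#'
#' @param cds DNA string, sense strand, frame 0 (U accepted).
#' @param table a [CodonUsageTable-class].
#' @param window window width in codons (default 18).
#' @param orfId label for the profile (defaults to "<cds>").
#' @param trim5 integer, codons to discard from the 5' end before
#'   profiling (default 0).
#' @return a [MinMaxProfile-class] with L - window + 1 values.
#' @examples
#' tab <- randomUsageTable(seed = 1, skew = 1)
#' p <- minMaxProfile(backtranslate(strrep("ACDEFGHIKLMNPQRSTVWY", 3), tab,
#'                                  mode = "max_codon"), tab)
#' all(profileValues(p) == 100)
#' @export
minMaxProfile <- function(cds, table, window = 18L, orfId = "<cds>",
                          trim5 = 0L) {
  window <- as.integer(window)
  if (window < 1L) .domainError("window must be a positive integer")
  cods <- .cdsCodons(cds, table@code, id = orfId)
  if (trim5 > 0L) {
    if (trim5 >= length(cods))
      .tooShortError(sprintf(
        "record '%s': trim5 = %d leaves no codons", orfId, trim5))
    cods <- cods[-seq_len(trim5)]
  }
  L <- length(cods)
  if (L < window)
    .tooShortError(sprintf(
      "record '%s' has %d sense codons, fewer than the %d-codon window",
      orfId, L, window))
  st <- .perCodonStats(table)
  idx <- match(cods, st$codon)
  A   <- .rollMean(st$f[idx], window)
  Max <- .rollMean(st$fMax[idx], window)
  Min <- .rollMean(st$fMin[idx], window)
  Avg <- .rollMean(st$fAvg[idx], window)
  up <- A >= Avg
  vals <- numeric(length(A))
  dHi <- Max - Avg
  dLo <- Avg - Min
  hi <- up & dHi > 0
  lo <- !up  # A < Avg implies Min <= A < Avg, so dLo > 0
  vals[hi] <- 100 * (A[hi] - Avg[hi]) / dHi[hi]
  vals[lo] <- -100 * (Avg[lo] - A[lo]) / dLo[lo]
  vals <- pmin(pmax(vals, -100), 100)
  new("MinMaxProfile", orfId = orfId, organismId = table@organismId,
      windowSize = window, values = vals,
      windowStart = 0:(L - window))
}
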