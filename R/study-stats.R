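#' CorrelationResult: Pearson r with two-tailed p
#'
#' @slot r Pearson correlation coefficient (NA when undefined).
#' @slot n integer sample size.
#' @slot p two-tailed p-value from the t transform (NA when undefined).
#' @slot defined logical; FALSE when either input had zero variance or
#'   fewer than 3 points, in which case the result is reported as an
#'   explicit undefined state rather than a silent NaN.
#' @seealso [pearsonWithP()]
#' @export
setClass("CorrelationResult",
  representation(r = "numeric", n = "integer", p = "numeric",
                 defined = "logical"))

setValidity("CorrelationResult", function(object) {
  if (object@defined && (is.na(object@r) || abs(object@r) > 1 + 1e-12))
    "defined result requires r in [-1, 1]" else TRUE
})

#' @describeIn pearsonWithP the correlation coefficient (NA if undefined)
#' @param x for the accessors, a [CorrelationResult-class].
#' @export
corCoef <- function(x) x@r

#' @describeIn pearsonWithP the sample size
#' @export
sampleSize <- function(x) x@n

#' @describeIn pearsonWithP the two-tailed p-value (NA if undefined)
#' @export
pValue <- function(x) x@p

#' @describeIn pearsonWithP TRUE when the correlation is defined
#' @export
isDefined <- function(x) x@defined

setMethod("show", "CorrelationResult", function(object) {
  if (object@defined)
    cat(sprintf("Pearson r = %.4f (n = %d, two-tailed p = %.3g)\n",
                object@r, object@n, object@p))
  else
    cat(sprintf("Pearson correlation undefined (n = %d)\n", object@n))
})

.undefinedCorrelation <- function(n) {
  new("CorrelationResult", r = NA_real_, n = as.integer(n), p = NA_real_,
      defined = FALSE)
}

#' Pearson correlation with a two-tailed p-value
#'
#' Computes r as the centered cross-product over the product of the
#' centered sums of squares, then the two-tailed p from
#' t = r sqrt((n-2)/(1-r^2)) against Student's t with n - 2 degrees of
#' freedom. With fewer than 3 points or a (numerically) zero-variance
#' input the result is flagged undefined instead of returning NaN; an
#' input whose standard deviation is below 1e-9 of its magnitude counts
#' as constant, so a flat profile carrying only rounding jitter is still
#' reported as undefined.
#'
#' @param x,y equal-length numeric vectors.
#' @return a [CorrelationResult-class].
#' @examples
#' res <- pearsonWithP(1:10, 2 * (1:10) + 1)
#' corCoef(res)  # 1
#' @export
pearsonWithP <- function(x, y) {
  if (length(x) != length(y))
    .alignmentError(sprintf("x has %d values, y has %d",
                            length(x), length(y)))
  n <- length(x)
  if (n < 3L) return(.undefinedCorrelation(n))
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx * dx)
  syy <- sum(dy * dy)
  nearZero <- function(ss, v) sqrt(ss / n) <= 1e-9 * (1 + max(abs(v)))
  if (nearZero(sxx, x) || nearZero(syy, y))
    return(.undefinedCorrelation(n))
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- min(max(r, -1), 1)
  p <- if (abs(r) == 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(abs(t), df = n - 2, lower.tail = FALSE)
  }
  new("CorrelationResult", r = r, n = as.integer(n), p = p, defined = TRUE)
}

#' Solubility fraction from band intensities
#'
#' The densitometric solubility of a protein at one condition: soluble-band
#' intensity over total (soluble + insoluble) intensity.
#'
#' @param iSf,iIf non-negative band intensities (soluble / insoluble
#'   fraction), vectorized.
#' @return solubility fraction(s) in [0, 1].
#' @examples
#' solubilityFraction(30, 70)  # 0.3
#' @export
solubilityFraction <- function(iSf, iIf) {
  if (any(iSf < 0 | iIf < 0))
    .domainError("band intensities must be non-negative")
  tot <- iSf + iIf
  if (any(tot == 0))
    .zeroIntensityError("soluble and insoluble intensities are both zero")
  iSf / tot
}

#' Classify a protein as soluble
#'
#' Soluble iff the solubility fraction strictly exceeds the threshold
#' (default 30%).
#'
#' @param fraction solubility fraction(s) in [0, 1].
#' @param threshold classification boundary (default 0.30).
#' @return logical vector.
#' @export
classifySoluble <- function(fraction, threshold = 0.30) {
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE))
    .domainError("solubility fraction must lie in [0, 1]")
  fraction > threshold
}

#' ConfusionMatrix: binary classifier counts
#'
#' @slot tp,tn,fp,fn non-negative integer counts.
#' @seealso [confusionMatrix()], [predictionAccuracy()], [mcc()]
#' @export
setClass("ConfusionMatrix",
  representation(tp = "integer", tn = "integer", fp = "integer",
                 fn = "integer"))

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(v < 0)) "counts must be non-negative"
  else if (sum(v) == 0) "confusion matrix must contain at least one case"
  else TRUE
})

#' Build a confusion matrix
#'
#' Either from explicit counts, or by comparing logical truth/prediction
#' vectors (TRUE = soluble/positive).
#'
#' @param truth,predicted equal-length logical vectors, or NULL when
#'   counts are given directly.
#' @param tp,tn,fp,fn explicit counts (used when `truth` is NULL).
#' @return a [ConfusionMatrix-class].
#' @examples
#' cm <- confusionMatrix(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' predictionAccuracy(cm)
#' @export
confusionMatrix <- function(truth = NULL, predicted = NULL,
                            tp = 0L, tn = 0L, fp = 0L, fn = 0L) {
  if (!is.null(truth)) {
    if (length(truth) != length(predicted))
      .alignmentError("truth and predicted lengths differ")
    tp <- sum(truth & predicted)
    tn <- sum(!truth & !predicted)
    fp <- sum(!truth & predicted)
    fn <- sum(truth & !predicted)
  }
  new("ConfusionMatrix", tp = as.integer(tp), tn = as.integer(tn),
      fp = as.integer(fp), fn = as.integer(fn))
}

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: TP %d, TN %d, FP %d, FN %d (PA %.3f, MCC %.3f)\n",
              object@tp, object@tn, object@fp, object@fn,
              predictionAccuracy(object), mcc(object)))
})

#' Classifier evaluation: prediction accuracy and MCC
#'
#' `predictionAccuracy` is (TN + TP) / (TN + FP + FN + TP). `mcc` is the
#' Matthews correlation coefficient
#' (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), defined as 0 by
#' convention when any factor in the denominator is zero (e.g. the
#' classifier predicts a single class).
#'
#' @param cm a [ConfusionMatrix-class].
#' @return a number in [0, 1] (`predictionAccuracy`) or [-1, 1] (`mcc`).
#' @export
predictionAccuracy <- function(cm) {
  (cm@tn + cm@tp) / (cm@tn + cm@fp + cm@fn + cm@tp)
}

#' @rdname predictionAccuracy
#' @export
mcc <- function(cm) {
  tp <- as.numeric(cm@tp); tn <- as.numeric(cm@tn)
  fp <- as.numeric(cm@fp); fn <- as.numeric(cm@fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Regression-band outlier exclusion
#'
#' Fits ordinary least squares y ~ x, computes the 95% band half-width at
#' every observed x, and excludes (in a single pass, no re-fitting) the
#' points whose absolute residual exceeds `multiplier` times their local
#' half-width. The band is the confidence band of the mean fit by
#' default; a prediction band (much wider, since it includes the residual
#' scatter) is available. Note that with a single-pass rule the two
#' behave very differently on small datasets: the confidence band flags
#' gross outliers reliably but also trims a tail of ordinary residuals,
#' while the 3x prediction band is inflated by the outlier itself and can
#' mask it. Residuals within numerical noise of zero are never excluded,
#' so exactly collinear data pass through untouched.
#'
#' @param x,y numeric vectors, n >= 4; x must have nonzero variance.
#' @param multiplier residual cut in units of band half-widths (default 3).
#' @param band `"confidence"` or `"prediction"`.
#' @param level band coverage (default 0.95).
#' @return list with `kept`, `excluded` (integer index vectors), `nExcluded`,
#'   `fit` (the `lm` object) and `halfWidth`.
#' @export
regressionOutlierFilter <- function(x, y, multiplier = 3,
                                    band = c("confidence", "prediction"),
                                    level = 0.95) {
  band <- match.arg(band)
  if (length(x) != length(y))
    .alignmentError("x and y lengths differ")
  if (length(x) < 4L)
    .domainError("outlier filtering needs at least 4 points")
  if (var(x) == 0)
    .fitError("x has zero variance; regression is degenerate")
  df <- data.frame(x = x, y = y)
  fit <- lm(y ~ x, data = df)
  pr <- predict(fit, newdata = df, interval = band, level = level)
  half <- pr[, "upr"] - pr[, "fit"]
  resid <- y - pr[, "fit"]
  guard <- sqrt(.Machine$double.eps) * (1 + max(abs(y)))
  excluded <- unname(which(abs(resid) > multiplier * half + guard))
  list(kept = setdiff(seq_along(x), excluded), excluded = excluded,
       nExcluded = length(excluded), fit = fit, halfWidth = unname(half))
}

#' Average discrete 0-5 expression/solubility scores
#'
#' Structural-genomics repositories report expression and solubility as
#' discrete scores from 0 (none/insoluble) to 5 (high/soluble); targets
#' with several reports are summarized by the arithmetic mean.
#'
#' @param scores integer vector, each value in 0..5.
#' @return the mean score.
#' @examples
#' spineAverage(c(3, 5))  # 4
#' @export
spineAverage <- function(scores) {
  if (length(scores) == 0)
    .domainError("no scores to average")
  if (any(is.na(scores)) || any(scores != as.integer(scores)) ||
      any(scores < 0 | scores > 5))
    .domainError("scores must be integers in 0..5")
  mean(scores)
}
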