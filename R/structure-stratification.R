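#' SSAnnotation: per-residue three-state secondary structure
#'
#' One character per residue of the translated CDS, over the alphabet
#' H (alpha-helix), E (beta-sheet), C (coil, i.e. neither helix nor sheet,
#' including disordered residues). `'-'`, `' '` and `'.'` in input are
#' normalized to C.
#'
#' @slot orfId label matching the annotated CDS.
#' @slot states character string over \{H, E, C\}.
#' @seealso [ssAnnotation()], [readSSAnnotation()]
#' @export
setClass("SSAnnotation",
  representation(orfId = "character", states = "character"))

setValidity("SSAnnotation", function(object) {
  if (grepl("[^HEC]", object@states))
    "states must use only H, E, C after normalization" else TRUE
})

#' Construct a secondary-structure annotation
#'
#' @param orfId label of the annotated ORF.
#' @param states string (or character vector of single states); lowercase
#'   accepted; `'-'`, `'.'` and blanks map to C. Any other character is a
#'   format error reporting its position.
#' @return an [SSAnnotation-class].
#' @examples
#' ssStates(ssAnnotation("x", "HHH---EEE"))  # "HHHCCCEEE"
#' @export
ssAnnotation <- function(orfId, states) {
  s <- toupper(paste(as.character(states), collapse = ""))
  s <- gsub("[-. ]", "C", s)
  bad <- regexpr("[^HEC]", s)
  if (bad != -1)
    .formatError(sprintf(
      "annotation '%s': unknown state '%s' at position %d",
      orfId, substr(s, bad, bad), bad))
  new("SSAnnotation", orfId = orfId, states = s)
}

#' @describeIn ssAnnotation the normalized H/E/C string
#' @param ann an [SSAnnotation-class].
#' @export
ssStates <- function(ann) ann@states

#' @describeIn ssAnnotation residue-level fraction of each class
#' @export
ssComposition <- function(ann) {
  b <- strsplit(ann@states, "")[[1]]
  c(H = mean(b == "H"), E = mean(b == "E"), C = mean(b == "C"))
}

setMethod("show", "SSAnnotation", function(object) {
  comp <- ssComposition(object)
  cat(sprintf(
    "SSAnnotation '%s': %d residues (H %.0f%%, E %.0f%%, C %.0f%%)\n",
    object@orfId, nchar(object@states), 100 * comp["H"], 100 * comp["E"],
    100 * comp["C"]))
})

#' Read secondary-structure annotations
#'
#' `"fasta-like"`: FASTA records whose sequences are H/E/C strings (one
#' record per protein, ids matching the CDS FASTA). `"jpred-jnet"`: a
#' JPred .jnet file; the comma-separated `jnetpred:` line is used, with
#' `-` mapped to coil; the record id defaults to the file base name.
#'
#' @param path file path.
#' @param format `"fasta-like"` or `"jpred-jnet"`.
#' @param orfId id override for the single-record jnet format.
#' @return a list of [SSAnnotation-class] (fasta-like) or a single
#'   [SSAnnotation-class] (jnet).
#' @export
readSSAnnotation <- function(path, format = c("fasta-like", "jpred-jnet"),
                             orfId = NULL) {
  format <- match.arg(format)
  if (format == "fasta-like") {
    recs <- Biostrings::readBStringSet(path)
    if (anyDuplicated(names(recs)))
      .manifestError("duplicate record ids in annotation FASTA")
    out <- lapply(seq_along(recs), function(i)
      ssAnnotation(names(recs)[i], as.character(recs[[i]])))
    names(out) <- names(recs)
    out
  } else {
    lines <- readLines(path, warn = FALSE)
    pred <- grep("^jnetpred:", lines, value = TRUE)
    if (!length(pred))
      .formatError("no 'jnetpred:' line in jnet file")
    states <- strsplit(sub("^jnetpred:", "", pred[1]), ",")[[1]]
    states <- states[states != ""]
    if (is.null(orfId))
      orfId <- tools::file_path_sans_ext(basename(path))
    ssAnnotation(orfId, paste(states, collapse = ""))
  }
}

#' Assign each %MinMax window to a secondary-structure class
#'
#' Under the `"center"` rule a window takes the class of its central
#' residue (0-based start + floor(W/2)); under `"majority"` it takes the
#' modal class of its W residues, ties broken H > E > C.
#'
#' @param ann an [SSAnnotation-class] covering the profiled CDS.
#' @param window window width in codons (default 18).
#' @param rule `"center"` or `"majority"`.
#' @return character vector of classes, one per window
#'   (length = residues - window + 1).
#' @export
assignWindowClasses <- function(ann, window = 18L,
                                rule = c("center", "majority")) {
  rule <- match.arg(rule)
  window <- as.integer(window)
  b <- strsplit(ann@states, "")[[1]]
  L <- length(b)
  if (L < window)
    .tooShortError(sprintf(
      "annotation '%s' has %d residues, fewer than the window (%d)",
      ann@orfId, L, window))
  nw <- L - window + 1L
  if (rule == "center") {
    b[seq_len(nw) + window %/% 2L]
  } else {
    vapply(seq_len(nw), function(i) {
      win <- b[i:(i + window - 1L)]
      counts <- c(H = sum(win == "H"), E = sum(win == "E"),
                  C = sum(win == "C"))
      names(counts)[which.max(counts)]  # which.max keeps H > E > C order
    }, "")
  }
}

#' Per-class %MinMax Correlation
#'
#' Splits the window set by secondary-structure class and computes the
#' Pearson correlation between the host and target profiles within each
#' class. A class with fewer than 3 windows (or zero variance within the
#' class) is reported as undefined.
#'
#' @param pHost,pTarget aligned [MinMaxProfile-class] objects.
#' @param ann [SSAnnotation-class] for the same CDS; its length must equal
#'   the number of profiled codons.
#' @param rule window-to-class rule, see [assignWindowClasses()].
#' @return named list H/E/C of [CorrelationResult-class].
#' @export
stratifiedMinMaxCorrelation <- function(pHost, pTarget, ann,
                                        rule = c("center", "majority")) {
  rule <- match.arg(rule)
  .checkComparable(pHost, pTarget)
  W <- pHost@windowSize
  nRes <- length(pHost@values) + W - 1L
  if (nchar(ann@states) != nRes)
    .pairingError(sprintf(
      "annotation '%s' has %d residues but the profile covers %d codons",
      ann@orfId, nchar(ann@states), nRes))
  classes <- assignWindowClasses(ann, window = W, rule = rule)
  out <- lapply(c(H = "H", E = "E", C = "C"), function(cl) {
    idx <- which(classes == cl)
    if (length(idx) < 3L) .undefinedCorrelation(length(idx))
    else pearsonWithP(pHost@values[idx], pTarget@values[idx])
  })
  out
}

#' Filter ORFs by secondary-structure content
#'
#' For dataset-level per-class analyses, keeps only the ORFs whose
#' residue-level fraction of the evaluated class strictly exceeds the
#' threshold (default 5%), so that a class correlation is never driven by
#' a protein that barely contains the structure.
#'
#' @param data data.frame with per-ORF class-fraction columns named
#'   `frac_H`, `frac_E`, `frac_C` (as produced by [runBatch()]).
#' @param class `"H"`, `"E"` or `"C"`.
#' @param threshold strict lower bound on the fraction (default 0.05).
#' @return the filtered data.frame.
#' @export
ssContentFilter <- function(data, class = c("H", "E", "C"),
                            threshold = 0.05) {
  class <- match.arg(class)
  col <- paste0("frac_", class)
  if (!col %in% names(data))
    .formatError(sprintf("data has no '%s' column", col))
  data[data[[col]] > threshold, , drop = FALSE]
}
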