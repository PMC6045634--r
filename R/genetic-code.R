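#' @import methods
#' @importFrom stats lm predict pt rnorm runif var sd setNames cor
#' @importFrom utils read.delim write.table
NULL

#' GeneticCode: codon-to-amino-acid mapping with synonymous-family structure
#'
#' Holds the 64-codon translation table plus, for each amino acid, the list
#' of its synonymous sense codons (its "family"). All codon-usage metrics in
#' the package are family-relative, so this object is passed around wherever
#' a codon has to be compared with its synonyms.
#'
#' @slot codonToAa named character vector of length 64; names are DNA codons
#'   over \{A,C,G,T\}, values one-letter amino acids with \code{"*"} for stop.
#' @slot families named list, one entry per amino acid, each a character
#'   vector of that amino acid's sense codons. Stop codons belong to no
#'   family.
#'
#' @seealso [geneticCode()], [standardGeneticCode()]
#' @export
setClass("GeneticCode",
  representation(codonToAa = "character", families = "list"))

setValidity("GeneticCode", function(object) {
  cta <- object@codonToAa
  msgs <- character(0)
  if (length(cta) != 64L)
    msgs <- c(msgs, "codonToAa must map exactly 64 codons")
  cods <- names(cta)
  if (is.null(cods) || any(nchar(cods) != 3L) ||
      any(grepl("[^ACGT]", cods)))
    msgs <- c(msgs, "codon names must be length-3 strings over {A,C,G,T}")
  if (anyDuplicated(cods))
    msgs <- c(msgs, "duplicate codons in codonToAa")
  fam <- unlist(object@families, use.names = FALSE)
  sense <- cods[cta != "*"]
  if (length(fam) != length(sense) || anyDuplicated(fam) ||
      !setequal(fam, sense))
    msgs <- c(msgs, "families must partition the sense codons")
  if (length(msgs)) msgs else TRUE
})

#' The standard genetic code
#'
#' Returns the standard (NCBI table 1) codon-to-amino-acid mapping as a
#' named character vector, taken from [Biostrings::GENETIC_CODE].
#'
#' @return named character vector, 64 codons, `"*"` marking stops.
#' @export
standardGeneticCode <- function() {
  x <- Biostrings::GENETIC_CODE
  setNames(as.character(x), names(x))
}

#' Construct a GeneticCode
#'
#' @param codonToAa named character vector mapping all 64 codons to
#'   one-letter amino acids (`"*"` = stop). Defaults to the standard code.
#' @return a [GeneticCode-class] object.
#' @examples
#' gc <- geneticCode()
#' senseCodons(gc)[1:5]
#' @export
geneticCode <- function(codonToAa = standardGeneticCode()) {
  codonToAa <- setNames(toupper(as.character(codonToAa)),
                        gsub("U", "T", toupper(names(codonToAa))))
  sense <- names(codonToAa)[codonToAa != "*"]
  families <- split(sense, codonToAa[sense])
  families <- lapply(families, sort)
  new("GeneticCode", codonToAa = codonToAa, families = families)
}

#' @describeIn geneticCode sense (non-stop) codons of a code
#' @param code a [GeneticCode-class] object.
#' @export
senseCodons <- function(code) {
  names(code@codonToAa)[code@codonToAa != "*"]
}

#' @describeIn geneticCode stop codons of a code
#' @export
stopCodons <- function(code) {
  names(code@codonToAa)[code@codonToAa == "*"]
}

#' @describeIn geneticCode synonymous-family list (amino acid -> codons)
#' @export
codonFamilies <- function(code) code@families

#' @describeIn geneticCode amino acid encoded by each codon in `codons`
#' @param codons character vector of codons.
#' @export
codonToAa <- function(code, codons) unname(code@codonToAa[codons])

setMethod("show", "GeneticCode", function(object) {
  cat("GeneticCode:", length(senseCodons(object)), "sense codons,",
      length(stopCodons(object)), "stop codons,",
      length(object@families), "synonymous families\n")
})

# --- sequence plumbing shared by every CDS-consuming operation ------------

# Normalizes a CDS string and returns its sense codons as a character
# vector: uppercases, maps U->T, enforces the ACGT alphabet and frame,
# strips one trailing stop codon, and rejects internal stops.
.cdsCodons <- function(cds, code, id = "<cds>") {
  s <- gsub("U", "T", toupper(as.character(cds)[1L]))
  if (nchar(s) == 0L)
    .domainError(sprintf("empty sequence for record '%s'", id))
  bad <- regmatches(s, regexpr("[^ACGT]", s))
  if (length(bad) && nchar(bad))
    .alphabetError(sprintf(
      "record '%s' contains non-ACGT character '%s'", id, bad))
  if (nchar(s) %% 3L != 0L)
    .frameError(sprintf(
      "record '%s' has length %d, not a multiple of 3", id, nchar(s)))
  cods <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  aa <- codonToAa(code, cods)
  n <- length(cods)
  if (aa[n] == "*") {
    cods <- cods[-n]
    aa <- aa[-n]
  }
  if (length(cods) == 0L)
    .domainError(sprintf("record '%s' has no sense codons", id))
  if (any(aa == "*"))
    .prematureStopError(sprintf(
      "record '%s' has internal stop codon at codon %d",
      id, which(aa == "*")[1L]))
  cods
}

#' Translate a coding sequence
#'
#' Translates a DNA CDS to protein under a [GeneticCode-class]. A single
#' trailing stop codon is dropped; an internal stop raises a
#' premature-stop error.
#'
#' @param cds DNA string (sense strand, frame 0; U accepted).
#' @param code a [GeneticCode-class]; default standard code.
#' @return one-letter amino-acid string.
#' @examples
#' translateCds("ATGAAATAA")  # "MK"
#' @export
translateCds <- function(cds, code = geneticCode()) {
  paste(codonToAa(code, .cdsCodons(cds, code)), collapse = "")
}
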