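#' CodonUsageTable: per-codon frequencies for one organism
#'
#' Frequencies are stored in occurrences per thousand codons (the Kazusa
#' convention). A table is complete when every sense codon of its genetic
#' code has a frequency; stop-codon frequencies may be present but are
#' ignored by all downstream metrics. Raw counts are kept when the table
#' was built from an ORF pool.
#'
#' @slot organismId character label.
#' @slot freq named numeric vector, codon -> frequency per thousand.
#' @slot counts named numeric vector of raw codon counts (length 0 when
#'   the table was not built from counts).
#' @slot sourceNOrfs integer, number of ORFs pooled (NA when unknown).
#' @slot code the [GeneticCode-class] defining the synonymous families.
#'
#' @seealso [codonUsageTable()], [codonUsageFromOrfs()], [readCodonUsage()]
#' @export
setClass("CodonUsageTable",
  representation(organismId = "character", freq = "numeric",
                 counts = "numeric", sourceNOrfs = "integer",
                 code = "GeneticCode"))

setValidity("CodonUsageTable", function(object) {
  msgs <- character(0)
  sense <- senseCodons(object@code)
  missing <- setdiff(sense, names(object@freq))
  if (length(missing))
    msgs <- c(msgs, paste("missing sense codons:",
                          paste(missing, collapse = ", ")))
  if (anyDuplicated(names(object@freq)))
    msgs <- c(msgs, "duplicate codons in freq")
  if (any(object@freq < 0))
    msgs <- c(msgs, "negative frequencies")
  if (length(object@counts) &&
      abs(sum(1000 * object@counts / sum(object@counts)) - 1000) > 1e-6)
    msgs <- c(msgs, "frequencies from counts must sum to 1000")
  if (length(msgs)) msgs else TRUE
})

#' Construct a codon usage table from frequencies
#'
#' @param freq named numeric vector codon -> frequency per thousand; must
#'   cover all sense codons of `code`. U in codon names is normalized to T.
#' @param organismId character label for the organism.
#' @param counts optional named numeric vector of raw codon counts.
#' @param sourceNOrfs optional integer, ORFs pooled to build the table.
#' @param code a [GeneticCode-class]; default standard code.
#' @return a [CodonUsageTable-class].
#' @export
codonUsageTable <- function(freq, organismId = "unknown", counts = numeric(0),
                            sourceNOrfs = NA_integer_, code = geneticCode()) {
  names(freq) <- gsub("U", "T", toupper(names(freq)))
  if (length(counts)) names(counts) <- gsub("U", "T", toupper(names(counts)))
  missing <- setdiff(senseCodons(code), names(freq))
  if (length(missing))
    .completenessError(paste("usage table missing sense codons:",
                             paste(missing, collapse = ", ")))
  if (anyDuplicated(names(freq)))
    .formatError(paste("duplicate codon in usage table:",
                       names(freq)[duplicated(names(freq))][1L]))
  new("CodonUsageTable", organismId = organismId,
      freq = freq, counts = counts,
      sourceNOrfs = as.integer(sourceNOrfs), code = code)
}

#' @describeIn codonUsageTable frequency-per-thousand vector (all tabulated
#'   codons)
#' @param table a [CodonUsageTable-class].
#' @export
codonFreq <- function(table) table@freq

#' @describeIn codonUsageTable raw counts (length 0 when unavailable)
#' @export
codonCounts <- function(table) table@counts

#' @describeIn codonUsageTable organism label
#' @export
organism <- function(table) table@organismId

#' @describeIn codonUsageTable the genetic code the table is defined over
#' @export
usageCode <- function(table) table@code

setMethod("show", "CodonUsageTable", function(object) {
  cat("CodonUsageTable for", object@organismId, "\n")
  cat(" ", length(object@freq), "codons tabulated;",
      if (length(object@counts)) sprintf("%d counted codons;",
                                         as.integer(sum(object@counts)))
      else "no raw counts;",
      if (is.na(object@sourceNOrfs)) "source ORFs unknown"
      else sprintf("built from %d ORFs", object@sourceNOrfs), "\n")
  sense <- senseCodons(object@code)
  cat("  sense freq sum:", format(sum(object@freq[sense]), digits = 6),
      "per thousand\n")
})

#' Build a codon usage table from a pool of ORFs
#'
#' Pools codon counts over a collection of coding sequences and converts
#' them to frequencies per thousand codons (Countcodon-style). Stop codons
#' are counted (they are part of the total) but flagged separately and
#' ignored by downstream metrics.
#'
#' @param orfs character vector of DNA coding sequences (or a
#'   `DNAStringSet`), each of length divisible by 3, A/C/G/T only
#'   (U normalized to T).
#' @param organismId label for the resulting table.
#' @param code a [GeneticCode-class].
#' @param skipAmbiguous if TRUE, codons containing non-ACGT characters are
#'   skipped instead of raising an alphabet error. Off by default.
#' @return a [CodonUsageTable-class] with counts and `sourceNOrfs` set.
#' @examples
#' tab <- codonUsageFromOrfs(c("ATGTGG", "TGGTGG"), organismId = "toy")
#' codonFreq(tab)[c("ATG", "TGG")]  # 250, 750
#' @export
codonUsageFromOrfs <- function(orfs, organismId = "unknown",
                               code = geneticCode(), skipAmbiguous = FALSE) {
  ids <- names(orfs)
  orfs <- as.character(orfs)
  if (is.null(ids)) ids <- paste0("orf", seq_along(orfs))
  allCodons <- c(senseCodons(code), stopCodons(code))
  counts <- setNames(numeric(length(allCodons)), allCodons)
  for (i in seq_along(orfs)) {
    s <- gsub("U", "T", toupper(orfs[[i]]))
    if (nchar(s) %% 3L != 0L)
      .frameError(sprintf(
        "ORF '%s' has length %d, not a multiple of 3", ids[i], nchar(s)))
    cods <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    bad <- grepl("[^ACGT]", cods)
    if (any(bad)) {
      if (!skipAmbiguous)
        .alphabetError(sprintf(
          "ORF '%s' contains non-ACGT codon '%s'", ids[i], cods[bad][1L]))
      cods <- cods[!bad]
    }
    tab <- table(cods)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  total <- sum(counts)
  if (total == 0)
    .domainError("ORF pool contains no codons")
  codonUsageTable(freq = 1000 * counts / total, organismId = organismId,
                  counts = counts, sourceNOrfs = length(orfs), code = code)
}

#' Read / write codon usage tables
#'
#' `readCodonUsage` reads either the package TSV dialect (columns
#' `codon`, `per_thousand` and optionally `count`, tab-separated, `#`
#' comments allowed) or Kazusa/Countcodon free text, i.e. whitespace
#' separated `CODON freq (count)` blocks with U or T codons.
#' `writeCodonUsage` writes the TSV dialect at full precision, so a
#' write/read round trip reproduces frequencies to better than 1e-9.
#'
#' @param path file path.
#' @param format `"tsv"` or `"kazusa"`.
#' @param organismId label for the table (defaults to the file base name).
#' @param code a [GeneticCode-class].
#' @return `readCodonUsage`: a [CodonUsageTable-class]; `writeCodonUsage`:
#'   the path, invisibly.
#' @export
readCodonUsage <- function(path, format = c("tsv", "kazusa"),
                           organismId = NULL, code = geneticCode()) {
  format <- match.arg(format)
  if (is.null(organismId))
    organismId <- tools::file_path_sans_ext(basename(path))
  if (format == "tsv") {
    df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    if (!all(c("codon", "per_thousand") %in% names(df)))
      .formatError("usage TSV needs columns 'codon' and 'per_thousand'")
    freq <- setNames(as.numeric(df$per_thousand), df$codon)
    counts <- if ("count" %in% names(df))
      setNames(as.numeric(df$count), df$codon) else numeric(0)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = " ")
    m <- gregexpr(
      "([ACGTUacgtu]{3})[ \t]+([0-9]+\\.?[0-9]*)[ \t]*\\(\\s*([0-9]+)\\s*\\)",
      txt)[[1]]
    if (m[1] == -1)
      .formatError("no 'CODON freq (count)' blocks found in Kazusa input")
    toks <- regmatches(txt, gregexpr(
      "([ACGTUacgtu]{3})[ \t]+([0-9]+\\.?[0-9]*)[ \t]*\\(\\s*([0-9]+)\\s*\\)",
      txt))[[1]]
    parts <- regmatches(toks, regexec(
      "([ACGTUacgtu]{3})[ \t]+([0-9]+\\.?[0-9]*)[ \t]*\\(\\s*([0-9]+)\\s*\\)",
      toks))
    cods <- vapply(parts, `[`, "", 2L)
    freq <- setNames(as.numeric(vapply(parts, `[`, "", 3L)), cods)
    counts <- setNames(as.numeric(vapply(parts, `[`, "", 4L)), cods)
  }
  names(freq) <- gsub("U", "T", toupper(names(freq)))
  if (anyDuplicated(names(freq)))
    .formatError(paste("duplicate codon in usage file:",
                       names(freq)[duplicated(names(freq))][1L]))
  codonUsageTable(freq = freq, organismId = organismId, counts = counts,
                  code = code)
}

#' @rdname readCodonUsage
#' @param table a [CodonUsageTable-class] to write.
#' @export
writeCodonUsage <- function(table, path) {
  freq <- table@freq
  df <- data.frame(codon = names(freq),
                   per_thousand = sprintf("%.17g", freq),
                   stringsAsFactors = FALSE)
  if (length(table@counts))
    df$count <- sprintf("%.17g", table@counts[names(freq)])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# codon usage table: %s", table@organismId), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-family frequency statistics
#'
#' For each amino-acid family, the maximum, minimum and unweighted mean of
#' the member codons' frequencies. These are the per-codon ceilings and
#' floors the %MinMax statistic is measured against.
#'
#' @param table a [CodonUsageTable-class].
#' @return data.frame with columns `aa`, `fMax`, `fMin`, `fAvg`, one row
#'   per amino acid.
#' @examples
#' tab <- codonUsageFromOrfs(c("GAAGAAGAAGAG"), organismId = "toy")
#' familyStats(tab)[c("E", "M"), ]
#' @export
familyStats <- function(table) {
  fams <- codonFamilies(table@code)
  freq <- table@freq
  res <- data.frame(
    aa = names(fams),
    fMax = vapply(fams, function(cs) max(freq[cs]), 0),
    fMin = vapply(fams, function(cs) min(freq[cs]), 0),
    fAvg = vapply(fams, function(cs) mean(freq[cs]), 0),
    row.names = names(fams), stringsAsFactors = FALSE)
  res
}

# Per-codon expansion of familyStats: for each sense codon, its own
# frequency plus its family's max/min/mean. The %MinMax inner loop indexes
# these four vectors directly.
.perCodonStats <- function(table) {
  fs <- familyStats(table)
  sense <- senseCodons(table@code)
  aa <- codonToAa(table@code, sense)
  list(codon = sense,
       f = unname(table@freq[sense]),
       fMax = fs[aa, "fMax"],
       fMin = fs[aa, "fMin"],
       fAvg = fs[aa, "fAvg"])
}

#' Relative adaptiveness of each codon
#'
#' w(c) = freq(c) / max family frequency: the most frequent codon of every
#' family gets w = 1. Codons with zero frequency receive a pseudocount so
#' that log(w) stays finite in the CAI: 0.5 / (family's maximum raw count)
#' when counts are available, otherwise 1e-3. A family whose codons all
#' have zero frequency raises a degenerate-family error.
#'
#' @param table a [CodonUsageTable-class].
#' @return named numeric vector over the sense codons, values in (0, 1].
#' @seealso [cai()]
#' @export
relativeAdaptiveness <- function(table) {
  fams <- codonFamilies(table@code)
  freq <- table@freq
  counts <- table@counts
  w <- setNames(numeric(0), character(0))
  for (aa in names(fams)) {
    cs <- fams[[aa]]
    fmax <- max(freq[cs])
    if (fmax == 0)
      .degenerateFamilyError(sprintf(
        "family '%s' has zero frequency for every codon", aa))
    wf <- freq[cs] / fmax
    zero <- wf == 0
    if (any(zero)) {
      wf[zero] <- if (length(counts)) 0.5 / max(counts[cs]) else 1e-3
    }
    w <- c(w, wf)
  }
  w[senseCodons(table@code)]
}
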