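# Readers/writers for the plain-text formats the pipeline consumes.
# Sequence I/O goes through Biostrings; tables are tab-separated with
# '#'-prefixed comment headers.

#' Read / write coding sequences
#'
#' Thin wrappers over Biostrings FASTA I/O that preserve record order,
#' reject duplicate ids, and return plain named character vectors (the
#' form the profiling functions take).
#'
#' @param path FASTA file path.
#' @return `readCds`: named character vector of DNA sequences;
#'   `writeCds`: the path, invisibly.
#' @export
readCds <- function(path) {
  recs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids))
    .manifestError(paste("duplicate FASTA ids:",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  setNames(as.character(recs), ids)
}

#' @rdname readCds
#' @param seqs named character vector of DNA sequences.
#' @export
writeCds <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a band-intensity table
#'
#' Tab-separated with columns `orf_id`, `temperature`, `I_sf`, `I_if` and
#' optionally `I_ladder`, `I_total`. Computes `solubility_fraction` (via
#' [solubilityFraction()]) and, when ladder columns are present,
#' `total_expression` = I_total / I_ladder.
#'
#' @param path TSV path.
#' @return data.frame with the derived columns appended.
#' @export
readIntensities <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("orf_id", "I_sf", "I_if")
  if (!all(need %in% names(df)))
    .formatError(paste("intensity TSV needs columns:",
                       paste(need, collapse = ", ")))
  df$solubility_fraction <- solubilityFraction(df$I_sf, df$I_if)
  if (all(c("I_ladder", "I_total") %in% names(df))) {
    if (any(df$I_ladder <= 0))
      .domainError("ladder band intensity must be positive")
    df$total_expression <- df$I_total / df$I_ladder
  }
  df
}

#' Read a SPINE-style score table
#'
#' Tab-separated with columns `orf_id`, `expression_scores`,
#' `solubility_scores`; the score columns hold semicolon-separated
#' discrete 0-5 values which are averaged per ORF (see [spineAverage()]).
#'
#' @param path TSV path.
#' @return data.frame with columns `orf_id`, `expression`, `solubility`.
#' @export
readSpineScores <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("orf_id", "expression_scores", "solubility_scores")
  if (!all(need %in% names(df)))
    .formatError(paste("SPINE TSV needs columns:",
                       paste(need, collapse = ", ")))
  avg <- function(s) spineAverage(as.numeric(strsplit(s, ";")[[1]]))
  data.frame(orf_id = df$orf_id,
             expression = vapply(df$expression_scores, avg, 0,
                                 USE.NAMES = FALSE),
             solubility = vapply(df$solubility_scores, avg, 0,
                                 USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Write a profile table
#'
#' Per-window TSV (orf_id, window_index, window_start_codon,
#' minmax_value) with a '#' comment header recording the table and window
#' size.
#'
#' @param profiles list of [MinMaxProfile-class].
#' @param path output path.
#' @export
writeProfileTable <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(profiles)) {
    w <- profiles[[1]]@windowSize
    org <- profiles[[1]]@organismId
    writeLines(sprintf("# %%MinMax profiles under '%s', window %d codons",
                       org, w), con)
  }
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(orf_id = p@orfId,
               window_index = seq_along(p@values) - 1L,
               window_start_codon = p@windowStart,
               minmax_value = p@values, stringsAsFactors = FALSE)))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
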