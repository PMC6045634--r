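# Batch orchestration: run every per-ORF metric over a dataset bundle and
# summarize dataset-level feature/outcome correlations.

#' Load a dataset bundle from files
#'
#' Reads the plain-text bundle written by [simulateStudy()] (or assembled
#' by hand): CDS FASTA, host/target usage TSVs, and optionally a
#' secondary-structure FASTA and an intensity TSV.
#'
#' @param paths named list with elements `cds`, `host`, `target` and
#'   optionally `ss`, `intensities` (file paths).
#' @return a `DatasetManifest` list usable with [runBatch()].
#' @export
loadManifest <- function(paths) {
  need <- c("cds", "host", "target")
  if (!all(need %in% names(paths)))
    .manifestError(paste("manifest needs paths:",
                         paste(need, collapse = ", ")))
  missing <- unlist(paths[!vapply(paths, is.null, TRUE)])
  missing <- missing[!file.exists(missing)]
  if (length(missing))
    .manifestError(paste("missing files:", paste(missing, collapse = ", ")))
  ss <- if (!is.null(paths$ss)) readSSAnnotation(paths$ss, "fasta-like")
  intensities <- if (!is.null(paths$intensities))
    readIntensities(paths$intensities)
  structure(list(cds = readCds(paths$cds),
                 hostTable = readCodonUsage(paths$host,
                                            organismId = "host"),
                 targetTable = readCodonUsage(paths$target,
                                              organismId = "target"),
                 ss = ss, intensities = intensities, truth = NULL,
                 config = NULL, paths = paths),
            class = "DatasetManifest")
}

# Cross-reference check: every auxiliary record must name a CDS id.
# All offending ids are enumerated before aborting.
.checkCrossRefs <- function(manifest) {
  ids <- names(manifest$cds)
  bad <- character(0)
  if (!is.null(manifest$ss))
    bad <- c(bad, setdiff(names(manifest$ss), ids))
  if (!is.null(manifest$intensities))
    bad <- c(bad, setdiff(manifest$intensities$orf_id, ids))
  if (length(bad))
    .manifestError(paste("records reference unknown ORF ids:",
                         paste(unique(bad), collapse = ", ")))
  invisible(TRUE)
}

#' Run the full per-ORF and dataset-level analysis
#'
#' For every CDS in the manifest: %MinMax profiles under the host and
#' target tables, delta %MinMax, %MinMax Correlation (overall and, when a
#' secondary-structure annotation is present, per H/E/C class), CAI under
#' the host table, and GC content; solubility fraction and total
#' expression are joined from the intensity table when present. Dataset
#' level: Pearson correlation of each feature against each outcome, plus
#' per-class correlations filtered by secondary-structure content (see
#' [ssContentFilter()]). Single-pass regression-band outlier exclusion
#' (see [regressionOutlierFilter()]) can be applied to the delta %MinMax
#' and %MinMax Correlation features; it is off by default because on
#' small screens the band rule also trims ordinary residuals and biases
#' the dataset-level p-values downward (the per-row `n_excluded` column
#' records what it removed when enabled).
#'
#' @param manifest a `DatasetManifest` from [simulateStudy()] or
#'   [loadManifest()].
#' @param window %MinMax window size in codons (default 18).
#' @param rule window-to-class assignment rule (default `"center"`).
#' @param trim5 codons trimmed from each CDS 5' end (default 0).
#' @param excludeOutliers apply the regression-band exclusion to the
#'   dataset-level delta/correlation analyses (default FALSE).
#' @param band band type for the exclusion rule.
#' @param solubleThreshold solubility classification boundary
#'   (default 0.30).
#' @return list with data.frames `perOrf` and `datasetCorrelations`.
#' @export
runBatch <- function(manifest, window = 18L, rule = c("center", "majority"),
                     trim5 = 0L, excludeOutliers = FALSE,
                     band = c("confidence", "prediction"),
                     solubleThreshold = 0.30) {
  rule <- match.arg(rule)
  band <- match.arg(band)
  .checkCrossRefs(manifest)
  ids <- names(manifest$cds)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    pH <- minMaxProfile(manifest$cds[[id]], manifest$hostTable,
                        window = window, orfId = id, trim5 = trim5)
    pT <- minMaxProfile(manifest$cds[[id]], manifest$targetTable,
                        window = window, orfId = id, trim5 = trim5)
    ann <- if (!is.null(manifest$ss)) manifest$ss[[id]] else NULL
    cmp <- compareProfiles(pH, pT, ann = ann, rule = rule)
    cr <- cmp@correlation
    row <- data.frame(
      orf_id = id, n_windows = cmp@nWindows,
      delta_minmax = cmp@deltaMinMax,
      minmax_corr_r = corCoef(cr), minmax_corr_p = pValue(cr),
      minmax_corr_defined = isDefined(cr),
      cai = cai(manifest$cds[[id]], manifest$hostTable, trim5 = trim5),
      gc = gcContent(manifest$cds[[id]]),
      stringsAsFactors = FALSE)
    if (!is.null(ann)) {
      comp <- ssComposition(ann)
      row$frac_H <- comp[["H"]]; row$frac_E <- comp[["E"]]
      row$frac_C <- comp[["C"]]
      for (cl in c("H", "E", "C")) {
        pc <- cmp@perClass[[cl]]
        row[[paste0("corr_", cl, "_r")]] <- corCoef(pc)
        row[[paste0("corr_", cl, "_p")]] <- pValue(pc)
        row[[paste0("corr_", cl, "_n")]] <- sampleSize(pc)
      }
    }
    rows[[i]] <- row
  }
  perOrf <- do.call(rbind, rows)
  if (!is.null(manifest$intensities)) {
    intens <- manifest$intensities
    if (!"solubility_fraction" %in% names(intens))
      intens$solubility_fraction <- solubilityFraction(intens$I_sf,
                                                       intens$I_if)
    if (!"total_expression" %in% names(intens) &&
        all(c("I_ladder", "I_total") %in% names(intens)))
      intens$total_expression <- intens$I_total / intens$I_ladder
    keep <- c("orf_id", "solubility_fraction",
              intersect("total_expression", names(intens)))
    perOrf <- merge(perOrf, intens[, keep, drop = FALSE],
                    by = "orf_id", sort = FALSE)
    perOrf$soluble_class <-
      classifySoluble(perOrf$solubility_fraction, solubleThreshold)
  }
  datasetCorrelations <-
    .datasetCorrelations(perOrf, excludeOutliers, band)
  list(perOrf = perOrf, datasetCorrelations = datasetCorrelations)
}

# One feature ~ outcome Pearson row, with optional outlier exclusion.
.corRow <- function(df, feature, outcome, exclude, band) {
  ok <- is.finite(df[[feature]]) & is.finite(df[[outcome]])
  x <- df[[feature]][ok]
  y <- df[[outcome]][ok]
  nExcluded <- 0L
  if (exclude && length(x) >= 4L && var(x) > 0) {
    filt <- regressionOutlierFilter(x, y, band = band)
    nExcluded <- filt$nExcluded
    x <- x[filt$kept]
    y <- y[filt$kept]
  }
  res <- pearsonWithP(x, y)
  data.frame(feature = feature, outcome = outcome,
             r = corCoef(res), p = pValue(res), n = sampleSize(res),
             n_excluded = nExcluded, stringsAsFactors = FALSE)
}

.datasetCorrelations <- function(perOrf, excludeOutliers, band) {
  outcomes <- intersect(c("solubility_fraction", "total_expression"),
                        names(perOrf))
  if (!length(outcomes)) return(NULL)
  rows <- list()
  defined <- perOrf[perOrf$minmax_corr_defined, , drop = FALSE]
  for (out in outcomes) {
    rows[[length(rows) + 1L]] <-
      .corRow(defined, "minmax_corr_r", out, excludeOutliers, band)
    rows[[length(rows) + 1L]] <-
      .corRow(perOrf, "delta_minmax", out, excludeOutliers, band)
    rows[[length(rows) + 1L]] <- .corRow(perOrf, "cai", out, FALSE, band)
    rows[[length(rows) + 1L]] <- .corRow(perOrf, "gc", out, FALSE, band)
  }
  # per-class correlation vs solubility, restricted to ORFs with > 5% of
  # the evaluated structure
  if ("solubility_fraction" %in% outcomes &&
      all(c("frac_H", "frac_E", "frac_C") %in% names(perOrf))) {
    for (cl in c("H", "E", "C")) {
      sub <- ssContentFilter(defined, cl)
      col <- paste0("corr_", cl, "_r")
      sub <- sub[is.finite(sub[[col]]), , drop = FALSE]
      rows[[length(rows) + 1L]] <-
        .corRow(sub, col, "solubility_fraction", excludeOutliers, band)
    }
  }
  do.call(rbind, rows)
}

#' Write batch reports
#'
#' Writes `per_orf.tsv` and `dataset_correlations.tsv` under `dir`, each
#' with a '#' comment header recording the package version and the flag
#' set used.
#'
#' @param report the list returned by [runBatch()].
#' @param dir output directory (created if missing).
#' @param flags named list echoed into the headers.
#' @return `dir`, invisibly.
#' @export
writeBatchReport <- function(report, dir, flags = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- c(sprintf("# codonMinMax %s",
                   as.character(utils::packageVersion("codonMinMax"))),
           sprintf("# %s = %s", names(flags),
                   vapply(flags, function(x) paste(format(x), collapse = ","),
                          "")))
  for (nm in c("perOrf", "datasetCorrelations")) {
    if (is.null(report[[nm]])) next
    path <- file.path(dir, paste0(
      c(perOrf = "per_orf", datasetCorrelations = "dataset_correlations")[nm],
      ".tsv"))
    con <- file(path, "w")
    writeLines(hdr, con)
    write.table(report[[nm]], con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
  }
  invisible(dir)
}
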