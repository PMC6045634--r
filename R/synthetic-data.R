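# Synthetic-data generator: random usage tables, back-translation under
# controllable codon-choice regimes, secondary-structure strings, and a
# complete simulated expression/solubility screen with planted effects.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Random codon usage table
#'
#' Draws a complete usage table whose within-family codon shares are
#' controlled by `skew`: each family's shares are proportional to
#' exp(skew * z) with z standard normal, so `skew = 0` gives exactly
#' uniform families (every gene's %MinMax profile is then identically 0)
#' and large `skew` concentrates each family on one dominant codon. Family
#' totals are proportional to family size; sense frequencies sum to 1000.
#'
#' @param seed optional integer; when supplied the RNG is seeded locally.
#' @param skew non-negative within-family concentration (default 1).
#' @param organismId label.
#' @param code a [GeneticCode-class].
#' @return a [CodonUsageTable-class].
#' @export
randomUsageTable <- function(seed = NULL, skew = 1, organismId = "sim",
                             code = geneticCode()) {
  if (skew < 0) .domainError("skew must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  fams <- codonFamilies(code)
  sense <- senseCodons(code)
  freq <- setNames(numeric(length(sense)), sense)
  for (aa in names(fams)) {
    cs <- fams[[aa]]
    share <- exp(skew * rnorm(length(cs)))
    share <- share / sum(share)
    freq[cs] <- 1000 * (length(cs) / length(sense)) * share
  }
  codonUsageTable(freq = freq, organismId = organismId, code = code)
}

# Within-family codon ordering used for rank-matching: decreasing
# frequency, ties broken lexicographically (codonFamilies() lists codons
# sorted, so order() tie-breaking on position is lexicographic).
.familyRanking <- function(table) {
  lapply(codonFamilies(table@code), function(cs) {
    f <- codonFreq(table)[cs]
    cs[order(-f, cs)]
  })
}

#' Back-translate a protein under a codon-choice regime
#'
#' Modes: `"max_codon"` picks each residue's most frequent codon (the
#' "one amino acid, one codon" optimization strategy); `"frequency_sampled"`
#' draws each codon with probability proportional to its within-family
#' frequency (a naturalistic gene under the table); `"uniform_random"`
#' draws uniformly within the family.
#'
#' @param protein amino-acid string over the 20 standard residues.
#' @param table a [CodonUsageTable-class] guiding codon choice.
#' @param mode codon-choice regime.
#' @param seed optional integer to seed the RNG locally.
#' @return DNA string, 3x protein length, translating back to `protein`.
#' @seealso [harmonizeCds()] for the rank-matching (harmonization) regime.
#' @export
backtranslate <- function(protein,
                          table,
                          mode = c("frequency_sampled", "max_codon",
                                   "uniform_random"),
                          seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit(toupper(as.character(protein)[1L]), "")[[1]]
  bad <- setdiff(unique(aa), .AA20)
  if (length(bad))
    .alphabetError(paste("unknown residue(s):", paste(bad, collapse = ", ")))
  fams <- codonFamilies(table@code)
  freq <- codonFreq(table)
  cods <- character(length(aa))
  for (a in unique(aa)) {
    pos <- which(aa == a)
    cs <- fams[[a]]
    cods[pos] <- switch(mode,
      max_codon = .familyRanking(table)[[a]][1L],
      frequency_sampled = {
        p <- freq[cs]
        if (sum(p) == 0) p <- rep(1, length(cs))
        cs[sample.int(length(cs), length(pos), replace = TRUE,
                      prob = p / sum(p))]
      },
      uniform_random =
        cs[sample.int(length(cs), length(pos), replace = TRUE)])
  }
  paste(cods, collapse = "")
}

#' Harmonize a coding sequence between two codon usage tables
#'
#' Rank-matching recoding: each codon of the source CDS is replaced by the
#' host-table codon occupying the same within-family frequency rank as the
#' source codon holds in the source table (ranks by decreasing frequency,
#' ties broken lexicographically). This reproduces the native gene's local
#' rare/common codon pattern under the host's usage, so the recoded gene's
#' %MinMax landscape under the host table mirrors the native landscape
#' under the source table.
#'
#' @param cds native DNA coding sequence.
#' @param sourceTable usage table of the native organism.
#' @param hostTable usage table of the expression host.
#' @return recoded DNA string (same protein, trailing stop dropped).
#' @export
harmonizeCds <- function(cds, sourceTable, hostTable) {
  cods <- .cdsCodons(cds, sourceTable@code)
  aa <- codonToAa(sourceTable@code, cods)
  srcRank <- .familyRanking(sourceTable)
  hostRank <- .familyRanking(hostTable)
  out <- vapply(seq_along(cods), function(i) {
    rk <- match(cods[i], srcRank[[aa[i]]])
    hostRank[[aa[i]]][rk]
  }, "")
  paste(out, collapse = "")
}

#' Configuration for a simulated expression/solubility screen
#'
#' Defaults emulate the scale of a small heterologous-expression screen:
#' 30 ORFs of 80-500 residues, host and target organisms with independent
#' skewed codon usage, secondary-structure composition 38% helix / 17%
#' sheet / 45% coil, and linear planted effects with Gaussian noise:
#' solubility = a + b * (%MinMax Correlation) + N(0, sigmaSol), clamped to
#' [0, 1]; expression = c - d * (delta %MinMax) + N(0, sigmaExpr), floored
#' at 0. The default coefficients place the planted line well inside the
#' observable range of each outcome (correlations span roughly -0.8 to
#' 0.85 between two independent tables, deltas roughly 20-90 percentage
#' points), so the clamps act only on rare noise tails and the planted
#' model stays effectively linear.
#'
#' @param seed integer RNG seed; a fixed seed makes the bundle
#'   byte-identical across runs.
#' @param nOrfs number of ORFs (default 30).
#' @param lengthRange protein length range in residues (default 80-500).
#' @param hostSkew,targetSkew within-family concentration of the two
#'   tables (default 1).
#' @param recoding codon-choice regime for the native CDSs.
#' @param a,b,sigmaSol planted solubility model (defaults 0.5, 0.4, 0.05).
#' @param cExpr,d,sigmaExpr planted expression model (defaults 5, 0.05,
#'   0.3).
#' @param ssProbs residue-level H/E/C probabilities.
#' @param window %MinMax window size used to generate the planted
#'   outcomes.
#' @return a `SimulationConfig` list (classed).
#' @seealso [simulateStudy()]
#' @export
simulationConfig <- function(seed = 1L, nOrfs = 30L,
                             lengthRange = c(80L, 500L),
                             hostSkew = 1, targetSkew = 1,
                             recoding = "frequency_sampled",
                             a = 0.5, b = 0.4, sigmaSol = 0.05,
                             cExpr = 5, d = 0.05, sigmaExpr = 0.3,
                             ssProbs = c(H = 0.38, E = 0.17, C = 0.45),
                             window = 18L) {
  if (sigmaSol < 0 || sigmaExpr < 0)
    .domainError("noise standard deviations must be non-negative")
  if (lengthRange[1] < 1 || lengthRange[2] < lengthRange[1])
    .domainError("invalid length range")
  structure(list(seed = as.integer(seed), nOrfs = as.integer(nOrfs),
                 lengthRange = as.integer(lengthRange),
                 hostSkew = hostSkew, targetSkew = targetSkew,
                 recoding = recoding, a = a, b = b, sigmaSol = sigmaSol,
                 cExpr = cExpr, d = d, sigmaExpr = sigmaExpr,
                 ssProbs = ssProbs / sum(ssProbs),
                 window = as.integer(window)),
            class = "SimulationConfig")
}

#' Simulate a complete expression/solubility screen
#'
#' Generates host and target codon usage tables, `nOrfs` coding sequences
#' (random proteins back-translated under the target table), per-residue
#' secondary-structure strings, and band-intensity data in which the
#' planted linear models tie solubility to the %MinMax Correlation and
#' total expression to the delta %MinMax of each ORF. When `dir` is given
#' the bundle is written as plain-text files (CDS FASTA, two usage TSVs,
#' SS FASTA, intensity TSV, JSON sidecar with the planted truth) and the
#' returned manifest carries their paths; otherwise everything stays in
#' memory.
#'
#' @param config a [simulationConfig()].
#' @param dir optional output directory (created if missing).
#' @return a list (classed `DatasetManifest`) with elements `cds`
#'   (named character), `hostTable`, `targetTable`, `ss` (list of
#'   [SSAnnotation-class]), `intensities` (data.frame), `truth`
#'   (planted values per ORF plus coefficients), `config`, and `paths`
#'   (NULL when `dir` is NULL).
#' @export
simulateStudy <- function(config = simulationConfig(), dir = NULL) {
  set.seed(config$seed)
  code <- geneticCode()
  hostTable <- randomUsageTable(skew = config$hostSkew,
                                organismId = "sim_host", code = code)
  targetTable <- randomUsageTable(skew = config$targetSkew,
                                  organismId = "sim_target", code = code)
  ids <- sprintf("orf_%03d", seq_len(config$nOrfs))
  lens <- sample(config$lengthRange[1]:config$lengthRange[2],
                 config$nOrfs, replace = TRUE)
  cds <- character(config$nOrfs)
  ss <- vector("list", config$nOrfs)
  corr <- numeric(config$nOrfs)
  delta <- numeric(config$nOrfs)
  for (i in seq_len(config$nOrfs)) {
    prot <- paste(sample(.AA20, lens[i], replace = TRUE), collapse = "")
    cds[i] <- backtranslate(prot, targetTable, mode = config$recoding)
    ss[[i]] <- ssAnnotation(ids[i], paste(
      sample(names(config$ssProbs), lens[i], replace = TRUE,
             prob = config$ssProbs), collapse = ""))
    pH <- minMaxProfile(cds[i], hostTable, window = config$window,
                        orfId = ids[i])
    pT <- minMaxProfile(cds[i], targetTable, window = config$window,
                        orfId = ids[i])
    cr <- minMaxCorrelation(pH, pT)
    corr[i] <- if (isDefined(cr)) corCoef(cr) else 0
    delta[i] <- deltaMinMax(pH, pT)
  }
  names(cds) <- ids
  names(ss) <- ids
  sol <- pmin(pmax(config$a + config$b * corr +
                     rnorm(config$nOrfs, 0, config$sigmaSol), 0), 1)
  expr <- pmax(config$cExpr - config$d * delta +
                 rnorm(config$nOrfs, 0, config$sigmaExpr), 0)
  # render solubility/expression as densitometry: a 100-unit total band
  # split soluble/insoluble, plus a target band against a unit ladder band
  intensities <- data.frame(
    orf_id = ids, temperature = "20C",
    I_sf = round(100 * sol, 6), I_if = round(100 * (1 - sol), 6),
    I_ladder = 1, I_total = round(expr, 6),
    stringsAsFactors = FALSE)
  truth <- list(a = config$a, b = config$b, sigmaSol = config$sigmaSol,
                cExpr = config$cExpr, d = config$d,
                sigmaExpr = config$sigmaExpr,
                perOrf = data.frame(orf_id = ids, minmax_correlation = corr,
                                    delta_minmax = delta, solubility = sol,
                                    expression = expr,
                                    stringsAsFactors = FALSE))
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      cds = file.path(dir, "cds.fasta"),
      host = file.path(dir, "host_usage.tsv"),
      target = file.path(dir, "target_usage.tsv"),
      ss = file.path(dir, "ss.fasta"),
      intensities = file.path(dir, "intensities.tsv"),
      truth = file.path(dir, "truth.json"))
    writeCds(cds, paths$cds)
    writeCodonUsage(hostTable, paths$host)
    writeCodonUsage(targetTable, paths$target)
    writeLines(unlist(lapply(ss, function(a)
      c(paste0(">", a@orfId), a@states))), paths$ss)
    write.table(intensities, paths$intensities, sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(
      list(a = truth$a, b = truth$b, sigmaSol = truth$sigmaSol,
           cExpr = truth$cExpr, d = truth$d, sigmaExpr = truth$sigmaExpr,
           perOrf = truth$perOrf),
      paths$truth, auto_unbox = TRUE, digits = NA)
  }
  structure(list(cds = cds, hostTable = hostTable,
                 targetTable = targetTable, ss = ss,
                 intensities = intensities, truth = truth,
                 config = config, paths = paths),
            class = "DatasetManifest")
}
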