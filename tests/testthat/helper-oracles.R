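# Independent brute-force oracles, coded separately from the package's
# vectorized paths, plus small fixture generators. Everything here is the
# "naive loop" version of the corresponding operation.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randProt <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

splitCodons <- function(cds) {
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

# brute-force pooled codon tally over ORF strings
oracleCountCodons <- function(orfs) {
  all <- unlist(lapply(orfs, splitCodons))
  counts <- table(factor(all, levels = sort(unique(all))))
  1000 * counts / sum(counts)
}

# per-family scan of max/min/mean
oracleFamilyStats <- function(tab) {
  fams <- codonFamilies(usageCode(tab))
  freq <- codonFreq(tab)
  do.call(rbind, lapply(names(fams), function(aa) {
    f <- freq[fams[[aa]]]
    data.frame(aa = aa, fMax = max(f), fMin = min(f), fAvg = mean(f))
  }))
}

# window-by-window %MinMax recomputation
oracleMinMax <- function(cds, tab, W = 18) {
  code <- usageCode(tab)
  fams <- codonFamilies(code)
  freq <- codonFreq(tab)
  cods <- splitCodons(cds)
  aa <- codonToAa(code, cods)
  if (aa[length(aa)] == "*") {
    cods <- cods[-length(cods)]
    aa <- aa[-length(aa)]
  }
  L <- length(cods)
  vapply(seq_len(L - W + 1), function(i) {
    win <- i:(i + W - 1)
    A  <- mean(freq[cods[win]])
    Mx <- mean(vapply(aa[win], function(a) max(freq[fams[[a]]]), 0))
    Mn <- mean(vapply(aa[win], function(a) min(freq[fams[[a]]]), 0))
    Av <- mean(vapply(aa[win], function(a) mean(freq[fams[[a]]]), 0))
    if (A >= Av) {
      if (Mx == Av) 0 else 100 * (A - Av) / (Mx - Av)
    } else {
      -100 * (Av - A) / (Av - Mn)
    }
  }, 0)
}

# direct transcription of the correlation formula + t transform
oraclePearson <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2))
  r <- num / den
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE))
}

# geometric mean of per-codon relative adaptiveness, recomputed by a
# family scan independent of relativeAdaptiveness()
oracleCai <- function(cds, tab) {
  code <- usageCode(tab)
  fams <- codonFamilies(code)
  freq <- codonFreq(tab)
  cods <- splitCodons(cds)
  aa <- codonToAa(code, cods)
  logw <- vapply(seq_along(cods), function(k) {
    log(freq[[cods[k]]] / max(freq[fams[[aa[k]]]]))
  }, 0)
  exp(sum(logw) / length(cods))
}

oracleMcc <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

# profile object with given values, for metric-level tests
makeProfile <- function(values, id = "p", org = "o", W = 18L) {
  new("MinMaxProfile", orfId = id, organismId = org,
      windowSize = as.integer(W), values = as.numeric(values),
      windowStart = 0:(length(values) - 1L))
}

# a gene built only from each family's rarest codon under `tab`
rarestCodonGene <- function(prot, tab) {
  fams <- codonFamilies(usageCode(tab))
  freq <- codonFreq(tab)
  aa <- strsplit(prot, "")[[1]]
  paste(vapply(aa, function(a) {
    cs <- fams[[a]]
    cs[order(freq[cs], cs)][1]
  }, ""), collapse = "")
}
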