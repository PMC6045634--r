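test_that("genetic code partitions the 64 codons into families", {
  gc <- geneticCode()
  expect_length(senseCodons(gc), 61)
  expect_length(stopCodons(gc), 3)
  expect_equal(sum(lengths(codonFamilies(gc))), 61)
  expect_equal(codonToAa(gc, c("ATG", "TGG", "TAA")), c("M", "W", "*"))
})

test_that("usage tables built from ORF pools match direct tallies", {
  expect_equal(codonFreq(codonUsageFromOrfs("ATGATG"))[["ATG"]], 1000)
  tab <- codonUsageFromOrfs(c("ATGTGG", "TGGTGG"))
  expect_equal(codonFreq(tab)[["ATG"]], 250)
  expect_equal(codonFreq(tab)[["TGG"]], 750)

  set.seed(101)
  orfs <- vapply(1:50, function(i)
    backtranslate(randProt(sample(20:60, 1)), randomUsageTable(skew = 1),
                  mode = "uniform_random"), "")
  tab <- codonUsageFromOrfs(orfs)
  expected <- oracleCountCodons(orfs)
  for (cod in names(expected))
    expect_equal(codonFreq(tab)[[cod]], unname(expected[cod]))

  # order invariance and concatenation vs separate records
  expect_equal(codonFreq(codonUsageFromOrfs(rev(orfs))), codonFreq(tab))
  expect_equal(codonFreq(codonUsageFromOrfs(paste(orfs, collapse = ""))),
               codonFreq(tab))
})

test_that("ORF pool validation names the offending record", {
  expect_error(codonUsageFromOrfs(c(a = "ATGT")), class = "frameError")
  expect_error(codonUsageFromOrfs(c(ok = "ATGTGG", bad = "ATGNNN")),
               regexp = "bad", class = "alphabetError")
  tab <- codonUsageFromOrfs(c("ATGNNNTGG"), skipAmbiguous = TRUE)
  expect_equal(codonFreq(tab)[["ATG"]], 500)
})

test_that("usage table TSV round trip is exact and Kazusa text parses", {
  set.seed(7)
  tab <- randomUsageTable(skew = 1.3, organismId = "rt")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCodonUsage(tab, path)
  back <- readCodonUsage(path)
  expect_equal(codonFreq(back)[names(codonFreq(tab))], codonFreq(tab),
               tolerance = 1e-12)

  kz <- withr::local_tempfile(fileext = ".txt")
  sense <- senseCodons(geneticCode())
  rna <- gsub("T", "U", sense)
  writeLines(paste(sprintf("%s 16.4 (%d)", rna, seq_along(rna) * 10),
                   collapse = "  "), kz)
  ktab <- readCodonUsage(kz, format = "kazusa")
  expect_equal(codonFreq(ktab)[["TTT"]], 16.4)
  expect_equal(codonCounts(ktab)[["TTT"]], 10 * which(sense == "TTT"))
})

test_that("incomplete or duplicated usage input is rejected by name", {
  freq <- setNames(rep(10, 61), senseCodons(geneticCode()))
  expect_error(codonUsageTable(freq[-which(names(freq) == "GCT")]),
               regexp = "GCT", class = "completenessError")
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(codon = c(names(freq), "GCT"),
                   per_thousand = c(freq, 10))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readCodonUsage(path), class = "formatError")
})

test_that("family statistics agree with a naive per-family scan", {
  freq <- setNames(rep(5, 61), senseCodons(geneticCode()))
  freq["GAA"] <- 30; freq["GAG"] <- 10
  tab <- codonUsageTable(freq)
  fs <- familyStats(tab)
  expect_equal(fs["E", c("fMax", "fMin", "fAvg")],
               data.frame(fMax = 30, fMin = 10, fAvg = 20, row.names = "E"))
  expect_equal(unlist(fs["M", c("fMax", "fMin", "fAvg")]),
               c(fMax = 5, fMin = 5, fAvg = 5))

  set.seed(11)
  for (i in 1:5) {
    tab <- randomUsageTable(skew = runif(1, 0, 2))
    fs <- familyStats(tab)
    orc <- oracleFamilyStats(tab)
    expect_equal(fs[orc$aa, "fMax"], orc$fMax)
    expect_equal(fs[orc$aa, "fMin"], orc$fMin)
    expect_equal(fs[orc$aa, "fAvg"], orc$fAvg)
    expect_true(all(fs$fMin <= fs$fAvg & fs$fAvg <= fs$fMax))
    # scaling the table scales every statistic
    tab3 <- codonUsageTable(codonFreq(tab) * 3)
    expect_equal(familyStats(tab3)$fAvg, fs$fAvg * 3)
  }
})

test_that("relative adaptiveness is the within-family frequency ratio", {
  freq <- setNames(rep(5, 61), senseCodons(geneticCode()))
  freq["GAA"] <- 30; freq["GAG"] <- 10
  w <- relativeAdaptiveness(codonUsageTable(freq))
  expect_equal(w[["GAA"]], 1)
  expect_equal(w[["GAG"]], 1 / 3)
  expect_equal(w[["ATG"]], 1)

  set.seed(13)
  tab <- randomUsageTable(skew = 1.5)
  w <- relativeAdaptiveness(tab)
  fams <- codonFamilies(usageCode(tab))
  freq <- codonFreq(tab)
  for (aa in names(fams)) {
    cs <- fams[[aa]]
    expect_equal(unname(w[cs]), unname(freq[cs] / max(freq[cs])))
    expect_equal(sum(w[cs] == 1), 1)  # unique max in a continuous draw
  }
})

test_that("zero-frequency codons get pseudocounts, degenerate families error", {
  # counts available: w = 0.5 / family max count. Pool covers every sense
  # codon once except GAG, plus extra GAA so the Glu family max count is 10.
  sense <- senseCodons(geneticCode())
  pool <- c(paste(setdiff(sense, "GAG"), collapse = ""), strrep("GAA", 9))
  tab <- codonUsageFromOrfs(pool)
  w <- relativeAdaptiveness(tab)
  expect_equal(w[["GAG"]], 0.5 / 10)
  # counts absent: fixed 1e-3
  freq <- setNames(rep(5, 61), senseCodons(geneticCode()))
  freq["GAG"] <- 0
  expect_equal(relativeAdaptiveness(codonUsageTable(freq))[["GAG"]], 1e-3)
  # a family with no observed codon at all cannot be normalized
  freq["GAA"] <- 0
  expect_error(relativeAdaptiveness(codonUsageTable(freq)),
               class = "degenerateFamilyError")
})
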