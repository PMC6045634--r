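test_that("random usage tables honor skew and determinism", {
  t1 <- randomUsageTable(seed = 5, skew = 1)
  t2 <- randomUsageTable(seed = 5, skew = 1)
  expect_identical(codonFreq(t1), codonFreq(t2))
  expect_equal(sum(codonFreq(t1)[senseCodons(geneticCode())]), 1000,
               tolerance = 1e-9)
  # skew 0: uniform families, so every profile is identically 0
  flat <- randomUsageTable(seed = 6, skew = 0)
  fs <- familyStats(flat)
  expect_equal(fs$fMax, fs$fMin)
  set.seed(61)
  cds <- backtranslate(randProt(40), flat, mode = "frequency_sampled")
  expect_equal(profileValues(minMaxProfile(cds, flat)), rep(0, 23))
  # large skew concentrates each family on one codon
  sharp <- randomUsageTable(seed = 7, skew = 6)
  set.seed(62)
  best <- backtranslate(randProt(30), sharp, mode = "max_codon")
  expect_equal(cai(best, sharp), 1)
  w <- relativeAdaptiveness(sharp)
  fams <- codonFamilies(geneticCode())
  secondBest <- vapply(fams[lengths(fams) > 1],
                       function(cs) sort(w[cs], decreasing = TRUE)[2], 0)
  expect_lt(median(secondBest), 0.05)
})

test_that("back-translation round-trips and honors each regime", {
  set.seed(63)
  tab <- randomUsageTable(skew = 1.2)
  prot <- randProt(60)
  for (mode in c("max_codon", "frequency_sampled", "uniform_random")) {
    cds <- backtranslate(prot, tab, mode = mode)
    expect_equal(translateCds(cds), prot)
  }
  expect_error(backtranslate("MKXW", tab), class = "alphabetError")
  # seeded draws are reproducible
  expect_identical(backtranslate(prot, tab, "frequency_sampled", seed = 9),
                   backtranslate(prot, tab, "frequency_sampled", seed = 9))
})

test_that("harmonization rank-matches and is invertible", {
  set.seed(64)
  src <- randomUsageTable(skew = 1, organismId = "src")
  host <- randomUsageTable(skew = 1, organismId = "host")
  cds <- backtranslate(randProt(80), src, mode = "frequency_sampled")
  h <- harmonizeCds(cds, src, host)
  expect_equal(translateCds(h), translateCds(cds))
  # rank matching is a within-family bijection, so harmonizing back
  # recovers the original coding sequence
  expect_equal(harmonizeCds(h, host, src), cds)
})

test_that("recoding regimes order the profile correlation as expected", {
  set.seed(65)
  src <- randomUsageTable(skew = 1, organismId = "src")
  host <- randomUsageTable(skew = 1, organismId = "host")
  rHarm <- rSamp <- numeric(20)
  for (i in 1:20) {
    prot <- randProt(120)
    native <- backtranslate(prot, src, mode = "frequency_sampled")
    pNative <- minMaxProfile(native, src)
    pHarm <- minMaxProfile(harmonizeCds(native, src, host), host)
    pSamp <- minMaxProfile(backtranslate(prot, host, "frequency_sampled"),
                           host)
    rHarm[i] <- corCoef(minMaxCorrelation(pHarm, pNative))
    rSamp[i] <- corCoef(minMaxCorrelation(pSamp, pNative))
    flat <- minMaxProfile(backtranslate(prot, host, "max_codon"), host)
    expect_false(isDefined(minMaxCorrelation(flat, pNative)))
  }
  expect_gt(median(rHarm), 0.5)
  expect_gt(median(rHarm), median(rSamp))
  expect_lt(abs(median(rSamp)), 0.4)
})

test_that("simulated bundles are deterministic and self-consistent", {
  cfg <- simulationConfig(seed = 11, nOrfs = 8, lengthRange = c(80, 150))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateStudy(cfg, dir = d1)
  simulateStudy(cfg, dir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # the written bundle passes every upstream validator on reload
  m <- loadManifest(list(cds = file.path(d1, "cds.fasta"),
                         host = file.path(d1, "host_usage.tsv"),
                         target = file.path(d1, "target_usage.tsv"),
                         ss = file.path(d1, "ss.fasta"),
                         intensities = file.path(d1, "intensities.tsv")))
  report <- runBatch(m)
  expect_equal(nrow(report$perOrf), 8)
  expect_true(all(c("delta_minmax", "minmax_corr_r", "cai", "gc",
                    "solubility_fraction", "total_expression")
                  %in% names(report$perOrf)))
  # lengths respect the 80-500 residue screen filter
  expect_true(all(nchar(m$cds) / 3 >= 80 & nchar(m$cds) / 3 <= 500))
})

test_that("regressing solubility on the computed correlation recovers b", {
  reps <- 200
  hits <- logical(reps)
  for (k in seq_len(reps)) {
    m <- simulateStudy(simulationConfig(seed = 7000 + k))
    fit <- lm(solubility ~ minmax_correlation, data = m$truth$perOrf)
    est <- coef(summary(fit))["minmax_correlation", ]
    hits[k] <- abs(est["Estimate"] - m$config$b) <= 2 * est["Std. Error"]
  }
  expect_gte(mean(hits), 0.9)
})
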