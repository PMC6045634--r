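test_that("annotation parsing normalizes to the H/E/C alphabet", {
  expect_equal(ssStates(ssAnnotation("x", "HHHEEECCC")), "HHHEEECCC")
  expect_equal(ssStates(ssAnnotation("x", "HHH---EEE")), "HHHCCCEEE")
  err <- tryCatch(ssAnnotation("x", "HHXE"), error = identity)
  expect_s3_class(err, "formatError")
  expect_match(conditionMessage(err), "position 3")
})

test_that("fasta-like and jnet annotation formats agree on a fixture", {
  states <- "HHHHEEEECCCCHHHCCC"
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">prot1", states), fa)
  jnet <- withr::local_tempfile(fileext = ".jnet")
  writeLines(c("align1;prot1",
               paste0("jnetpred:",
                      paste(gsub("C", "-", strsplit(states, "")[[1]]),
                            collapse = ","), ","),
               "JNETCONF:9999999999999999"), jnet)
  fromFa <- readSSAnnotation(fa, "fasta-like")[["prot1"]]
  fromJnet <- readSSAnnotation(jnet, "jpred-jnet", orfId = "prot1")
  expect_equal(ssStates(fromJnet), ssStates(fromFa))
})

test_that("window class assignment follows the center and majority rules", {
  allH <- ssAnnotation("a", strrep("H", 30))
  expect_equal(assignWindowClasses(allH), rep("H", 13))
  # 9 helix then 9 sheet residues: the single window's center residue
  # (0-based index 9) is a sheet residue
  half <- ssAnnotation("b", paste0(strrep("H", 9), strrep("E", 9)))
  expect_equal(assignWindowClasses(half, rule = "center"), "E")
  # majority rule ties break H > E > C
  expect_equal(assignWindowClasses(half, rule = "majority"), "H")

  set.seed(41)
  for (i in 1:10) {
    L <- sample(20:60, 1)
    states <- paste(sample(c("H", "E", "C"), L, TRUE), collapse = "")
    ann <- ssAnnotation("r", states)
    got <- assignWindowClasses(ann, rule = "majority")
    b <- strsplit(states, "")[[1]]
    naive <- vapply(1:(L - 17), function(j) {
      counts <- table(factor(b[j:(j + 17)], levels = c("H", "E", "C")))
      names(counts)[which.max(counts)]
    }, "")
    expect_equal(got, naive)
    # center rule only reads window-center residues
    centers <- (1:(L - 17)) + 9
    b2 <- b; b2[-centers] <- sample(c("H", "E", "C"), L - length(centers),
                                    TRUE)
    expect_equal(assignWindowClasses(ssAnnotation("r2",
                                                  paste(b2, collapse = "")),
                                     rule = "center"),
                 assignWindowClasses(ann, rule = "center"))
  }
})

test_that("per-class correlations partition the window set", {
  set.seed(42)
  host <- randomUsageTable(skew = 1, organismId = "h")
  target <- randomUsageTable(skew = 1, organismId = "t")
  for (i in 1:5) {
    L <- sample(60:120, 1)
    cds <- backtranslate(randProt(L), target, mode = "frequency_sampled")
    ann <- ssAnnotation("g", paste(
      sample(c("H", "E", "C"), L, TRUE, prob = c(0.38, 0.17, 0.45)),
      collapse = ""))
    pH <- minMaxProfile(cds, host, orfId = "g")
    pT <- minMaxProfile(cds, target, orfId = "g")
    res <- stratifiedMinMaxCorrelation(pH, pT, ann)
    expect_named(res, c("H", "E", "C"))
    expect_equal(sum(vapply(res, sampleSize, 0L)), L - 17L)
    # subset-then-correlate oracle per class
    classes <- assignWindowClasses(ann)
    for (cl in c("H", "E", "C")) {
      idx <- which(classes == cl)
      if (length(idx) >= 3) {
        orc <- oraclePearson(profileValues(pH)[idx], profileValues(pT)[idx])
        expect_equal(corCoef(res[[cl]]), orc$r, tolerance = 1e-12)
      } else {
        expect_false(isDefined(res[[cl]]))
      }
    }
  }
})

test_that("degenerate stratifications collapse to the expected results", {
  set.seed(43)
  host <- randomUsageTable(skew = 1, organismId = "h")
  target <- randomUsageTable(skew = 1, organismId = "t")
  cds <- backtranslate(randProt(50), target, mode = "frequency_sampled")
  pH <- minMaxProfile(cds, host); pT <- minMaxProfile(cds, target)
  allCoil <- ssAnnotation("g", strrep("C", 50))
  res <- stratifiedMinMaxCorrelation(pH, pT, allCoil)
  expect_equal(corCoef(res$C), corCoef(minMaxCorrelation(pH, pT)))
  expect_false(isDefined(res$H))
  expect_false(isDefined(res$E))
  # same table on both sides: every defined class correlation is 1
  mixed <- ssAnnotation("g", paste(rep(c("H", "E", "C"), length.out = 50),
                                   collapse = ""))
  same <- stratifiedMinMaxCorrelation(pH, pH, mixed)
  for (cl in names(same))
    if (isDefined(same[[cl]])) expect_equal(corCoef(same[[cl]]), 1)
  expect_error(
    stratifiedMinMaxCorrelation(pH, pT, ssAnnotation("g", strrep("C", 49))),
    class = "pairingError")
})

test_that("the 5% structure-content filter is strict", {
  rows <- data.frame(
    orf_id = c("lowE", "edgeE", "balanced"),
    frac_H = c(0.50, 0.45, 0.38),
    frac_E = c(0.04, 0.05, 0.17),
    frac_C = c(0.46, 0.50, 0.45))
  expect_equal(ssContentFilter(rows, "E")$orf_id, "balanced")
  for (cl in c("H", "E", "C"))
    expect_true("balanced" %in% ssContentFilter(rows, cl)$orf_id)
})
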