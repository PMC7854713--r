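test_that("ratio series take pointwise log10 ratios at common detections", {
  p <- writeTidyCsv(list(
    tidyRow(na = "RNA", rna = "rRNA", t = 0, copies = "100"),
    tidyRow(na = "RNA", rna = "rRNA", t = 24, copies = "10"),
    tidyRow(na = "DNA", rna = "rRNA", t = 0, copies = "10"),
    tidyRow(na = "DNA", rna = "rRNA", t = 24, copies = "10")))
  de <- readMeasurements(p)
  rs <- buildRatioSeries(de, "RD")
  expect_length(rs, 1L)
  expect_equal(rs[[1]]@log10Ratio, c(1, 0))
  expect_equal(rs[[1]]@timeH, c(0, 24))
  expect_identical(rs[[1]]@numerator, "16S_141_RNA")

  # censored denominator drops the shared timepoint and counts the omission
  p2 <- writeTidyCsv(list(
    tidyRow(na = "RNA", t = 0, copies = "100"),
    tidyRow(na = "RNA", t = 24, copies = "10"),
    tidyRow(na = "DNA", t = 0, copies = "10"),
    tidyRow(na = "DNA", t = 24, copies = "", cens = "TRUE")))
  rs2 <- buildRatioSeries(readMeasurements(p2), "RD")
  expect_equal(rs2[[1]]@timeH, 0)
  expect_equal(rs2[[1]]@nOmitted, 1L)

  # identical numerator and denominator: all-zero log ratios
  de0 <- simulateExperiment(pairConfig(kR = 0.05, kD = 0.05,
                                       c0R = 7, c0D = 7))
  rs0 <- buildRatioSeries(de0, "RD")
  expect_true(all(vapply(rs0, function(s)
    max(abs(s@log10Ratio)) < 1e-12, logical(1))))
})

test_that("short:long pairing follows amplicon length within a gene family", {
  de <- simulateExperiment(defaultSimConfig(seed = 1))
  rs <- suppressWarnings(buildRatioSeries(de, "SL"))
  pairs <- unique(vapply(rs, function(s)
    paste(s@numerator, s@denominator, sep = "/"), character(1)))
  expect_setequal(pairs, c("16S_141_DNA/16S_341_DNA",
                           "H2B_75_DNA/H2B_250_DNA"))
})

test_that("the pooled log-ratio slope equals -(kRNA - kDNA)/ln(10)", {
  de <- simulateExperiment(pairConfig())
  rr <- regressRatio(buildRatioSeries(de, "RD"))
  expect_equal(rr@slope, -(0.0561 - 0.0378) / log(10), tolerance = 1e-12)
  expect_equal(rr@r2, 1, tolerance = 1e-12)
  # equal decay constants: flat ratio
  rr0 <- regressRatio(buildRatioSeries(
    simulateExperiment(pairConfig(kR = 0.05, kD = 0.05)), "RD"))
  expect_equal(rr0@slope, 0, tolerance = 1e-12)
  expect_equal(rr0@pValue, 1)
})

test_that("degenerate ratio regressions are refused", {
  df <- data.frame(time_h = c(0, 24), log10_ratio = c(1, 0))
  expect_error(regressRatio(df), "at least 3")
  df2 <- data.frame(time_h = c(0, 0, 0), log10_ratio = c(1, 1.1, 0.9))
  expect_error(regressRatio(df2), "degenerate")
})

test_that("the age estimator inverts differential decay", {
  ae <- estimateAge(observed = 1, baseline = 3, kRna = 0.0561, kDna = 0.0378)
  expect_equal(tHat(ae), log(10) * 2 / 0.0183, tolerance = 1e-12)
  expect_equal(tHat(ae), 251.6486, tolerance = 1e-4)
  expect_equal(tHat(estimateAge(2, 2, 0.06, 0.04)), 0)
  expect_warning(ae0 <- estimateAge(3.5, 3, 0.06, 0.04), "fresh")
  expect_equal(tHat(ae0), 0)
  expect_error(estimateAge(1, 3, 0.04, 0.06), "kRna must exceed")
  # strictly increasing in the ratio drop, decreasing in delta k
  drops <- seq(0.5, 3, by = 0.5)
  ages <- vapply(drops, function(d)
    tHat(estimateAge(3 - d, 3, 0.06, 0.04)), numeric(1))
  expect_true(all(diff(ages) > 0))
  dks <- seq(0.01, 0.05, by = 0.01)
  ages2 <- vapply(dks, function(dk)
    tHat(estimateAge(1, 3, 0.04 + dk, 0.04)), numeric(1))
  expect_true(all(diff(ages2) < 0))
})

test_that("bootstrap intervals contain the estimate and are reproducible", {
  a1 <- estimateAge(1, 3, 0.0561, 0.0378, seKRna = 0.0025, seKDna = 0.0025,
                    seObserved = 0.3, seed = 11)
  a2 <- estimateAge(1, 3, 0.0561, 0.0378, seKRna = 0.0025, seKDna = 0.0025,
                    seObserved = 0.3, seed = 11)
  expect_identical(a1@ciH, a2@ciH)
  expect_true(a1@ciH[1] <= tHat(a1) && tHat(a1) <= a1@ciH[2])
  expect_gt(a1@ciH[2], a1@ciH[1])
  # all-known inputs: degenerate interval at the estimate
  a0 <- estimateAge(1, 3, 0.0561, 0.0378)
  expect_equal(a0@ciH, rep(tHat(a0), 2))
})

test_that("a noiseless tank is dated exactly at every sampling time", {
  cfg <- pairConfig(timepoints = c(0, 7, 33.5, 101, 240))
  de <- simulateExperiment(cfg)
  rs <- buildRatioSeries(de, "RD")
  s <- rs[[1]]
  base <- s@log10Ratio[s@timeH == 0]
  for (i in seq_along(s@timeH)) {
    ae <- estimateAge(s@log10Ratio[i], base, 0.0561, 0.0378)
    expect_equal(tHat(ae), s@timeH[i], tolerance = 1e-9)
  }
})

test_that("the age recovery study is exact without noise", {
  cfg <- pairConfig(abundances = c(2, 6), replicates = 2L,
                    timepoints = c(0, 12, 24, 48, 72))
  st <- ageRecoveryStudy(cfg, sampleTimes = c(12, 48), reps = 3, seed = 5,
                         nboot = 50)
  expect_equal(st$bias_h, c(0, 0), tolerance = 1e-9)
  expect_equal(st$rmse_h, c(0, 0), tolerance = 1e-9)
  expect_equal(st$coverage, c(1, 1))
})

test_that("age estimates stay calibrated under experiment-scale noise", {
  cfg <- pairConfig(seed = 1, noise = 0.5, tank_sd = 0.3, lod = 0.6)
  st <- ageRecoveryStudy(cfg, sampleTimes = c(12, 24, 48, 72), reps = 120,
                         seed = 7, excludeTankIds = c("A06_B", "A24_B"),
                         nboot = 400)
  expect_true(all(abs(st$bias_h) < st$rmse_h))
  # uncertainty grows with age at fixed delta k
  expect_gt(st$rmse_h[4], st$rmse_h[1])
  expect_true(all(st$coverage >= 0.90 & st$coverage <= 1))
})
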