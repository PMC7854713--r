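test_that("normalisation rescales a series to C0 = 1", {
  tg <- GeneTarget("16S_141", "mt", "rRNA", 141, "DNA")
  s <- ConcentrationSeries("T1", tg, c(0, 1, 2), c(100, 50, 25))
  n <- normalizeSeries(s)
  expect_identical(n@copiesPerMl, c(1, 0.5, 0.25))
  # censored C0 makes the series unusable
  s2 <- ConcentrationSeries("T1", tg, c(0, 1), c(NA, 50),
                            censored = c(TRUE, FALSE))
  expect_error(normalizeSeries(s2), "t = 0")
  # degenerate single-point series
  s3 <- ConcentrationSeries("T1", tg, 0, 42)
  expect_identical(normalizeSeries(s3)@copiesPerMl, 1)
  # censored points stay censored
  s4 <- ConcentrationSeries("T1", tg, c(0, 1, 2), c(100, NA, 25),
                            censored = c(FALSE, TRUE, FALSE))
  n4 <- normalizeSeries(s4)
  expect_identical(n4@censored, c(FALSE, TRUE, FALSE))
  expect_true(is.na(n4@copiesPerMl[2]))
})

test_that("noiseless data are fitted exactly", {
  cfg <- singleTargetConfig(c0_log = 9, k = 0.05,
                            timepoints = c(0, 5, 12, 24, 48, 72),
                            abundances = c(2, 6, 12), replicates = 2L)
  de <- simulateExperiment(cfg)
  fit <- fitDecay(de, method = "two-stage")
  expect_equal(kHat(fit@fits[[1]]), 0.05, tolerance = 1e-12)
  expect_equal(seK(fit@fits[[1]]), 0, tolerance = 1e-10)
  # all ten default targets recovered exactly without noise or effects
  cfg10 <- defaultSimConfig(seed = 2)
  cfg10@tankSd <- 0; cfg10@noiseSd <- 0
  cfg10@abundanceC0Slope <- 0; cfg10@abundanceKSlope <- 0
  cfg10@lodCopiesPerMl <- 0
  de10 <- simulateExperiment(cfg10)
  fit10 <- fitDecay(de10, method = "two-stage")
  truth <- cfg10@targets$k
  truth[is.na(truth)] <- cfg10@fallbackK
  expect_equal(resultsTable(fit10)$k, truth, tolerance = 1e-10)
})

test_that("the fitted slope is invariant to concentration units", {
  cfg <- singleTargetConfig(seed = 3, c0_log = 9, k = 0.05,
                            timepoints = c(0, 5, 12, 24, 48, 72),
                            abundances = c(2, 6, 12), replicates = 2L,
                            noise = 0.4)
  cfg_scaled <- cfg
  cfg_scaled@targets$c0_log <- cfg@targets$c0_log + log(1000)
  k1 <- resultsTable(fitDecay(simulateExperiment(cfg),
                              method = "two-stage"))$k
  k2 <- resultsTable(fitDecay(simulateExperiment(cfg_scaled),
                              method = "two-stage"))$k
  expect_equal(k1, k2, tolerance = 1e-10)
})

test_that("dropping the censored tail does not move a noiseless slope", {
  cfg <- singleTargetConfig(c0_log = 5, k = 0.05,
                            timepoints = c(0, 12, 24, 48, 72))
  k_full <- resultsTable(fitDecay(simulateExperiment(cfg),
                                  method = "two-stage"))$k
  cfg@lodCopiesPerMl <- exp(5 - 0.05 * 40)  # censors t = 48, 72
  de <- simulateExperiment(cfg)
  expect_equal(detectionCount(de), 3L)
  k_cens <- resultsTable(fitDecay(de, method = "two-stage"))$k
  expect_equal(k_full, k_cens, tolerance = 1e-12)
})

test_that("mixed and two-stage estimators agree on balanced noisy designs", {
  de <- excludeTanks(simulateExperiment(defaultSimConfig(seed = 31)),
                     c("A06_B", "A24_B"))
  f1 <- fitDecay(de, method = "mixed")
  f2 <- fitDecay(de, method = "two-stage")
  expect_identical(f1@method, "mixed")
  t1 <- resultsTable(f1); t2 <- resultsTable(f2)
  expect_true(all(abs(t1$k - t2$k) <=
                    2 * sqrt(t1$se^2 + t2$se^2) + 1e-12))
})

test_that("the refuse censoring policy raises on censored points", {
  cfg <- singleTargetConfig(c0_log = 5, k = 0.05,
                            timepoints = c(0, 12, 24, 48, 72),
                            lod = exp(5 - 0.05 * 40))
  de <- simulateExperiment(cfg)
  expect_error(fitDecay(de, censorPolicy = "refuse"), "censored")
  expect_silent(fitDecay(de, censorPolicy = "drop", method = "two-stage"))
})

test_that("targets censored everywhere are flagged, not errors", {
  tg <- data.frame(
    gene = c("16S_141", "COI_128"), genome = "mt",
    rna_class = c("rRNA", "mRNA"), amplicon_length = c(141L, 128L),
    nucleic_acid = "DNA", c0_log = c(9, -10), k = c(0.05, 0.05),
    stringsAsFactors = FALSE)
  cfg <- SimConfig(seed = 2, abundances = c(2, 6), replicatesPerAbundance = 2L,
                   timepointsH = c(0, 12, 24, 48), targets = tg,
                   lodCopiesPerMl = 0.6)
  de <- simulateExperiment(cfg)
  fit <- fitDecay(de, method = "two-stage")
  tab <- resultsTable(fit)
  expect_true(tab$estimable[tab$gene == "16S_141"])
  expect_false(tab$estimable[tab$gene == "COI_128"])
  expect_true(is.na(tab$k[tab$gene == "COI_128"]))
  ic <- fitInitialConcentration(de)
  expect_false(resultsTable(ic)$estimable[2])
})

test_that("initial concentrations are recovered exactly without noise", {
  cfg <- defaultSimConfig(seed = 2)
  cfg@tankSd <- 0; cfg@noiseSd <- 0
  cfg@abundanceC0Slope <- 0; cfg@abundanceKSlope <- 0
  cfg@lodCopiesPerMl <- 0
  de <- simulateExperiment(cfg)
  ic <- fitInitialConcentration(de)
  expect_equal(resultsTable(ic)$estimate, cfg@targets$c0_log,
               tolerance = 1e-8)
  expect_true(all(resultsTable(ic)$se < 1e-6))
  # two targets with identical truth: contrast ties exactly at p = 1
  cfg_eq <- pairConfig(kR = 0.05, kD = 0.05, c0R = 7, c0D = 7)
  ic_eq <- fitInitialConcentration(simulateExperiment(cfg_eq))
  ct <- contrastTable(ic_eq)
  expect_equal(ct$estimate, 0, tolerance = 1e-10)
  expect_gt(ct$adjusted_p, 0.05)
})

test_that("replicated studies recover the 18S rRNA release concentration", {
  # Monte-Carlo over full default experiments: the marginal intercept of the
  # highest-concentration marker must be unbiased at the simulated truth
  reps <- 60
  est <- numeric(reps)
  for (i in seq_len(reps)) {
    de <- excludeTanks(simulateExperiment(defaultSimConfig(seed = 5000 + i)),
                       c("A06_B", "A24_B"))
    ic <- fitInitialConcentration(de)
    est[i] <- resultsTable(ic)$estimate[
      resultsTable(ic)$target == "18S_169_RNA"]
  }
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 12.61), 3 * mc_se + 0.02)
})

test_that("pairwise contrasts recover the RNA - DNA decay difference", {
  de <- simulateExperiment(pairConfig())
  fit <- fitDecay(de, method = "two-stage")
  ct <- pairwiseContrasts(fit, "nucleic_acid")
  expect_equal(nrow(ct), 1L)
  d <- if (ct$group_a == "RNA") ct$estimate else -ct$estimate
  expect_equal(d, 0.0561 - 0.0378, tolerance = 1e-10)
  # identical fits tie exactly with p = 1
  cfg_eq <- pairConfig(kR = 0.05, kD = 0.05)
  ct_eq <- pairwiseContrasts(fitDecay(simulateExperiment(cfg_eq),
                                      method = "two-stage"), "nucleic_acid")
  expect_equal(ct_eq$estimate, 0, tolerance = 1e-12)
  expect_equal(ct_eq$adjusted_p, 1)
  # k groups: three abundance levels give three pairwise contrasts
  cfg3 <- singleTargetConfig(seed = 4, c0_log = 9, k = 0.05,
                             timepoints = c(0, 12, 24, 48, 72),
                             abundances = c(2, 12, 48), replicates = 3L,
                             noise = 0.3)
  fit3 <- fitDecay(simulateExperiment(cfg3), method = "two-stage")
  expect_equal(nrow(pairwiseContrasts(fit3, "abundance")), 3L)
  # single group: empty result with a warning
  expect_warning(
    out <- pairwiseContrasts(fitDecay(simulateExperiment(
      singleTargetConfig(timepoints = c(0, 12, 24))), method = "two-stage"),
      "genome"),
    "fewer than 2")
  expect_equal(nrow(out), 0L)
})

test_that("interval coverage of k is close to nominal under noise", {
  cfg <- pairConfig(seed = 1, noise = 0.5, tank_sd = 0.3, lod = 0.6)
  st <- decayRecoveryStudy(cfg, target = "16S_141_RNA", reps = 120,
                           seed = 77, excludeTankIds = c("A06_B", "A24_B"))
  expect_lt(abs(st$summary$mean_k_hat - 0.0561), 3 * st$summary$mc_se)
  expect_gte(st$summary$coverage, 0.89)
  expect_lte(st$summary$coverage, 1.00)
})
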