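test_that("noiseless simulation follows the closed-form decay law", {
  de <- simulateExperiment(singleTargetConfig())
  expect_equal(unname(assay(de, "copies")[1, ]), c(100, 50, 25))
  # log-linear identity at every timepoint
  cfg <- singleTargetConfig(k = 0.05, timepoints = c(0, 5, 12, 24, 48, 72))
  de2 <- simulateExperiment(cfg)
  lr <- log(assay(de2, "copies")[1, ] / assay(de2, "copies")[1, 1])
  expect_equal(unname(lr), -0.05 * cfg@timepointsH, tolerance = 1e-12)
})

test_that("the detection limit censors exactly the sub-LOD observations", {
  de <- simulateExperiment(singleTargetConfig(lod = 30))
  expect_equal(unname(assay(de, "censored")[1, ]), c(FALSE, FALSE, TRUE))
  expect_true(is.na(assay(de, "copies")[1, 3]))
  expect_equal(detectionCount(de), 2L)
})

test_that("the default design yields 15 tanks x 10 targets x 8 times", {
  de <- simulateExperiment(defaultSimConfig(seed = 1))
  expect_equal(dim(de), c(10L, 120L))
  expect_equal(sum(!is.na(assay(de, "censored"))), 1200L)
  expect_length(unique(colData(de)$tank_id), 15L)
})

test_that("the default configuration carries the published kinetic truths", {
  cfg <- defaultSimConfig()
  tg <- cfg@targets
  expect_equal(cfg@timepointsH, c(0, 5, 12, 24, 48, 72, 144, 240))
  r16d <- tg[tg$gene == "16S_141" & tg$nucleic_acid == "DNA", ]
  expect_equal(r16d$c0_log, 4.75)
  expect_equal(r16d$k, 0.0378)
  r18r <- tg[tg$gene == "18S_169" & tg$nucleic_acid == "RNA", ]
  expect_equal(r18r$c0_log, 12.61)
  expect_equal(r18r$k, 0.0735)
  # the H2B messenger-RNA target has no measured constant: fallback applies
  expect_true(is.na(tg$k[tg$gene == "H2B_250" & tg$nucleic_acid == "RNA"]))
  expect_equal(cfg@abundances, c(2, 6, 12, 24, 48))
  expect_equal(cfg@replicatesPerAbundance, 3L)
})

test_that("simulation is bit-reproducible given the seed", {
  a <- simulateExperiment(defaultSimConfig(seed = 11))
  b <- simulateExperiment(defaultSimConfig(seed = 11))
  d <- simulateExperiment(defaultSimConfig(seed = 12))
  expect_identical(assay(a, "copies"), assay(b, "copies"))
  expect_identical(assay(a, "censored"), assay(b, "censored"))
  expect_false(identical(assay(a, "copies"), assay(d, "copies")))
})

test_that("simulating does not disturb the caller's RNG stream", {
  set.seed(99)
  x1 <- runif(1)
  set.seed(99)
  invisible(simulateExperiment(defaultSimConfig(seed = 2)))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("raising the detection limit never adds detections", {
  for (seed in c(2, 23, 77)) {
    lods <- c(0, 0.6, 5, 50, 500)
    des <- lapply(lods, function(l)
      simulateExperiment(defaultSimConfig(seed = seed, lodCopiesPerMl = l)))
    dets <- vapply(des, detectionCount, integer(1))
    expect_true(all(diff(dets) <= 0))
    # nesting: every detection at a higher LOD is a detection at a lower one
    for (i in seq_len(length(lods) - 1)) {
      hi <- !assay(des[[i + 1]], "censored")
      lo <- !assay(des[[i]], "censored")
      expect_true(all(lo[hi]))
    }
  }
})

test_that("censoring fraction is non-decreasing in time under decay", {
  for (seed in c(4, 8, 15)) {
    cfg <- singleTargetConfig(seed = seed, c0_log = 4.75, k = 0.0378,
                              timepoints = c(0, 5, 12, 24, 48, 72, 144, 240),
                              abundances = c(2, 6, 12, 24, 48),
                              replicates = 24L, noise = 0.5, lod = 0.6)
    de <- simulateExperiment(cfg)
    cn <- assay(de, "censored")
    tm <- colData(de)$time_h
    frac <- vapply(sort(unique(tm)), function(t)
      mean(cn[, tm == t]), numeric(1))
    expect_true(all(diff(frac) >= 0))
  }
})

test_that("tank intercepts and noise average out to the latent log-mean", {
  # 1000 replicate tanks at one abundance; fixed t, lognormal noise only
  cfg <- singleTargetConfig(seed = 6, c0_log = 8, k = 0.05,
                            timepoints = c(0, 24), replicates = 1000L,
                            noise = 0.5)
  de <- simulateExperiment(cfg)
  tm <- colData(de)$time_h
  obs <- log(assay(de, "copies")[1, tm == 24])
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - (8 - 0.05 * 24)), 3 * se)
})

test_that("simulated truth ledger matches the generated data", {
  cfg <- defaultSimConfig(seed = 21)
  de <- simulateExperiment(cfg)
  tr <- simTruth(de)
  expect_s4_class(tr, "SimTruth")
  expect_equal(nrow(tr@params), 150L)  # 15 tanks x 10 targets
  # noiseless experiment: observations equal the latent surface
  cfg0 <- singleTargetConfig(k = 0.1, timepoints = c(0, 10, 20))
  de0 <- simulateExperiment(cfg0)
  expect_equal(assay(de0, "copies"), simTruth(de0)@latent)
  # latent invariant: exp(c0 + tank effect) * exp(-k t)
  p <- simTruth(de)@params
  i <- match(colData(de)$tank_id, p$tank_id[p$target == "16S_141_DNA"])
  lat <- exp(p$c0_log[p$target == "16S_141_DNA"][i] -
               p$k[p$target == "16S_141_DNA"][i] * colData(de)$time_h)
  expect_equal(unname(simTruth(de)@latent["16S_141_DNA", ]), lat)
})

test_that("biphasic decay slows by the configured multiplier after the break", {
  cfg <- singleTargetConfig(c0_log = 10, k = 0.1,
                            timepoints = c(0, 12, 24, 36, 48),
                            biphasic = list(breakpoint_h = 24,
                                            k_multiplier_after = 0.5))
  de <- simulateExperiment(cfg)
  lc <- log(assay(de, "copies")[1, ])
  expect_equal(unname(lc[1:3]), 10 - 0.1 * c(0, 12, 24))
  expect_equal(unname(lc[4:5]), 10 - 0.1 * 24 - 0.05 * c(12, 24))
})

test_that("invalid configurations are rejected", {
  expect_error(SimConfig(targets = NULL), "target")
  expect_error(singleTargetConfig(timepoints = c(5, 12)), "start at 0")
  expect_error(singleTargetConfig(timepoints = c(0, 5, 5)), "ascending")
  expect_error(singleTargetConfig(noise = -1), ">= 0")
  expect_error(
    singleTargetConfig(biphasic = list(breakpoint_h = 24,
                                       k_multiplier_after = 1.5)),
    "0, 1")
})
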