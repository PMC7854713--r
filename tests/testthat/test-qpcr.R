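test_that("a perfect-efficiency dilution series is recovered exactly", {
  copies <- c(1, 10, 100, 1000)
  sc <- fitStandardCurve(copies, 40 - 3.321928 * log10(copies))
  expect_equal(sc@slope, -3.321928, tolerance = 1e-9)
  expect_equal(sc@intercept, 40, tolerance = 1e-9)
  expect_equal(efficiency(sc), 1, tolerance = 1e-6)
  expect_equal(sc@r2, 1, tolerance = 1e-12)
})

test_that("efficiency follows 10^(-1/slope) - 1 and is monotone in slope", {
  sc <- fitStandardCurve(c(1, 10, 100, 1000),
                         38 - 3.59 * log10(c(1, 10, 100, 1000)))
  expect_equal(efficiency(sc), 10^(1 / 3.59) - 1, tolerance = 1e-12)
  expect_equal(efficiency(sc), 0.899116, tolerance = 1e-6)
  slopes <- seq(-4.2, -2.8, by = 0.2)
  effs <- vapply(slopes, function(s) 10^(-1 / s) - 1, numeric(1))
  expect_true(all(diff(effs) > 0))
})

test_that("degenerate standard curves are refused", {
  expect_error(fitStandardCurve(c(1, 10), c(40, 36.7)), "3 distinct")
  expect_error(fitStandardCurve(c(1, 10, 100), c(30, 33, 36)),
               "slope must be negative")
  expect_error(fitStandardCurve(c(0, 10, 100), c(40, 36, 33)), "positive")
})

test_that("Cq inverts to copies along the fitted line", {
  sc <- fitStandardCurve(10^(0:5), 40 - 3.321928 * (0:5))
  expect_equal(cqToCopies(40, sc), 1, tolerance = 1e-9)
  expect_equal(cqToCopies(36.678072, sc), 10, tolerance = 1e-6)
  # one slope unit of Cq = tenfold template; strictly decreasing in Cq
  expect_equal(cqToCopies(35 + sc@slope, sc) / cqToCopies(35, sc), 10,
               tolerance = 1e-9)
  cqs <- seq(20, 40, by = 2.5)
  expect_true(all(diff(cqToCopies(cqs, sc)) < 0))
  expect_true(is.na(cqToCopies(NA_real_, sc)))
})

test_that("curve fitting and inversion round-trip colinear dilutions", {
  set.seed(31)
  for (i in 1:5) {
    slope <- runif(1, -3.8, -3.0)
    intercept <- runif(1, 34, 42)
    copies <- 10^(0:6)
    cq <- intercept + slope * log10(copies)
    sc <- fitStandardCurve(copies, cq)
    expect_equal(cqToCopies(cq, sc), copies, tolerance = 1e-6)
    expect_equal(copiesToCq(copies, sc), cq, tolerance = 1e-9)
  }
})

test_that("the Cq > 35 rule censors exactly the records it names", {
  rec <- data.frame(sample = c("a", "b", "c", "d"),
                    cq = c(34.9, 35, 35.1, NA))
  out <- applyDetectionLimit(rec)
  expect_equal(out$censored, c(FALSE, FALSE, TRUE, TRUE))
  # idempotent
  expect_identical(applyDetectionLimit(out)$censored, out$censored)
  # configurable threshold
  expect_equal(applyDetectionLimit(rec, thresholdCq = 34)$censored,
               c(TRUE, TRUE, TRUE, TRUE))
  expect_error(applyDetectionLimit(rec, thresholdCq = 0), "positive")
  expect_error(applyDetectionLimit(data.frame(x = 1)), "cq")
})

test_that("the volume bridge rescales copies per reaction to copies per mL", {
  expect_equal(copiesPerReactionToPerMl(100, 2), 50)
  expect_equal(copiesPerReactionToPerMl(100, 1), 100)
  # default encodes 2.5 uL of 75 uL eluate from half of 100 mL filtered
  expect_equal(copiesPerReactionToPerMl(1), 0.6)
  expect_error(copiesPerReactionToPerMl(100, 0), "positive")
  expect_error(copiesPerReactionToPerMl(100, -2), "positive")
})
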