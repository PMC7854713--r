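test_that("the decay curve evaluates C0 exp(-k t)", {
  expect_equal(decayCurve(100, 0, 123), 100)
  expect_equal(decayCurve(1, log(2), 1), 0.5)
  expect_equal(decayCurve(100, 0.0378, 72), 100 * exp(-2.7216))
  expect_equal(decayCurve(100, 0.0378, 72), 6.578, tolerance = 1e-3)
  expect_error(decayCurve(-1, 0.1, 1), ">= 0")
  expect_error(decayCurve(1, -0.1, 1), ">= 0")
  expect_error(decayCurve(1, 0.1, -1), ">= 0")
})

test_that("decay composes over time (semigroup property)", {
  set.seed(12)
  for (i in 1:20) {
    c0 <- runif(1, 1, 1e6); k <- runif(1, 0, 0.2)
    t1 <- runif(1, 0, 100); t2 <- runif(1, 0, 100)
    expect_equal(decayCurve(c0, k, t1 + t2),
                 decayCurve(decayCurve(c0, k, t1), k, t2),
                 tolerance = 1e-12)
  }
})

test_that("half-life inverts the decay constant", {
  expect_equal(halfLife(log(2)), 1)
  expect_equal(halfLife(0.0378), 18.337, tolerance = 1e-4)
  # published nu-18S rRNA constant: half-life inside the printed range
  expect_equal(halfLife(0.0735), 9.4306, tolerance = 1e-4)
  expect_gt(halfLife(0.0735), 8.84)
  expect_lt(halfLife(0.0735), 10.09)
  ks <- seq(0.01, 0.2, by = 0.01)
  expect_true(all(diff(halfLife(ks)) < 0))
  expect_error(halfLife(0), "> 0")
})

test_that("half-life intervals invert the Wald bounds of k", {
  set.seed(5)
  for (i in 1:20) {
    k <- runif(1, 0.02, 0.2); se <- runif(1, 0, k / 3)
    ci <- halfLifeInterval(k, se)
    expect_lt(ci[1], ci[2] + 1e-12)
    expect_true(ci[1] <= halfLife(k) && halfLife(k) <= ci[2])
  }
  expect_equal(halfLifeInterval(0.1, 0), rep(halfLife(0.1), 2))
  expect_error(halfLifeInterval(0.01, 0.01), "crosses 0")
  expect_error(halfLifeInterval(0, 0.001), "> 0")
})
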