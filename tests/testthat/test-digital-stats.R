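# Poisson occupancy mathematics: molecule arithmetic, occupancy pmf,
# active-fraction transforms, absolute quantification and the digital-regime
# check.

test_that("molecule arithmetic reproduces the printed design points", {
  # 40 uL at 1031 aM: C V N_A = 1031e-18 * 40e-6 * 6.022e23 = 24834.7
  n <- moleculesInSample(SampleSpec(1031, 40))
  expect_equal(n, 1031 * 40 * 0.6022, tolerance = 1e-12)
  expect_equal(signif(n, 2), 25000)
  expect_equal(moleculesInSample(SampleSpec(0, 40)), 0)
  expect_equal(round(moleculesInSample(SampleSpec(2.6, 40))), 63)
  # dilution scales down linearly
  expect_equal(moleculesInSample(SampleSpec(1031, 40, dilutionFactor = 2)),
               n / 2)
})

test_that("SampleSpec rejects invalid inputs", {
  expect_error(SampleSpec(-1, 40), "non-negative")
  expect_error(SampleSpec(10, 0), "positive")
  expect_error(SampleSpec(10, 40, dilutionFactor = 0.5), ">= 1")
})

test_that("occupancy pmf matches the digital design condition", {
  # the single-or-empty design probability at lambda = 0.1
  p01 <- occupancyPmf(0.1, 0) + occupancyPmf(0.1, 1)
  expect_equal(p01, exp(-0.1) * 1.1, tolerance = 1e-12)
  expect_gte(p01, 0.99)
  expect_identical(occupancyPmf(0, 0), 1)
  # closed-form multiple occupancy
  expect_equal(multipleOccupancyProb(0.1), 1 - exp(-0.1) * 1.1,
               tolerance = 1e-12)
  expect_equal(multipleOccupancyProb(0.1), 4.679e-3, tolerance = 1e-4)
  expect_equal(occupancyPmf(0.1, 2), 4.524e-3, tolerance = 1e-4)
  expect_error(occupancyPmf(-0.1, 0), "non-negative")
  expect_error(occupancyPmf(0.1, -1), "non-negative")
})

test_that("occupancy pmf sums to one and matches Monte-Carlo draws", {
  for (lam in c(0, 0.01, 0.1, 1, 5))
    expect_equal(sum(occupancyPmf(lam, 0:200)), 1, tolerance = 1e-12)
  # independent Monte-Carlo cross-check of P(k >= 2) at lambda = 0.1
  set.seed(4242)
  draws <- rpois(1e6, 0.1)
  mc <- mean(draws >= 2)
  se <- sqrt(mc * (1 - mc) / 1e6)
  expect_lt(abs(mc - multipleOccupancyProb(0.1)), 3 * se + 1e-12)
})

test_that("expected active fraction and its inverse are exact partners", {
  expect_equal(expectedActiveFraction(0.1), 0.09516, tolerance = 1e-4)
  expect_equal(round(expectedActiveFraction(0.1), 1), 0.1)  # "10%"
  expect_identical(expectedActiveFraction(0), 0)
  expect_equal(expectedActiveFraction(-log(0.5)), 0.5, tolerance = 1e-12)
  # strict monotonicity
  lam <- seq(0, 3, by = 0.05)
  expect_true(all(diff(expectedActiveFraction(lam)) > 0))
  # round trip to 1e-10 over lambda in [0, 3]
  expect_equal(occupancyFromFraction(expectedActiveFraction(lam)), lam,
               tolerance = 1e-10)
  expect_identical(occupancyFromFraction(0), 0)
  expect_error(expectedActiveFraction(-1), "non-negative")
  expect_error(occupancyFromFraction(0.999999), "satur")
  expect_error(occupancyFromFraction(1), "satur")
})

test_that("Clopper-Pearson intervals match the exact binomial test", {
  for (case in list(c(5, 100), c(0, 50), c(617, 6480), c(50, 50))) {
    est <- ActiveFractionEstimate(case[1], case[2])
    expect_lte(est$ciLow, est$fraction)
    expect_gte(est$ciHigh, est$fraction)
    ref <- binom.test(case[1], case[2])$conf.int
    expect_equal(c(est$ciLow, est$ciHigh), as.numeric(ref),
                 tolerance = 1e-9)
  }
  expect_error(ActiveFractionEstimate(10, 5), "<=")
})

test_that("absolute concentration estimation inverts the forward model", {
  sample <- SampleSpec(0, 40)  # concentration field unused
  # lambda = 0.1 on 250,000 pillars: N = 25,000 molecules ->
  # C = 25000 / (40 * 0.6022) = 1037.86 aM
  est <- ActiveFractionEstimate(round(expectedActiveFraction(0.1) * 1e6),
                                1e6)
  out <- estimateConcentration(est, 250000, sample)
  expect_equal(out$concentration, 25000 / (40 * 0.6022), tolerance = 1e-3)
  expect_lt(out$ciLow, out$concentration)
  expect_gt(out$ciHigh, out$concentration)
  # zero count: 0 aM with a one-sided interval
  z <- estimateConcentration(ActiveFractionEstimate(0, 6480), 250000, sample)
  expect_identical(z$concentration, 0)
  expect_identical(z$ciLow, 0)
  expect_gt(z$ciHigh, 0)
  # doubling the dilution doubles the estimate at fixed fraction
  s2 <- SampleSpec(0, 40, dilutionFactor = 2)
  e <- ActiveFractionEstimate(617, 6480)
  expect_equal(estimateConcentration(e, 250000, s2)$concentration,
               2 * estimateConcentration(e, 250000, sample)$concentration)
  # strictly monotone in the active count
  cs <- vapply(c(10, 100, 500, 1000), function(k)
    estimateConcentration(ActiveFractionEstimate(k, 6480), 250000,
                          sample)$concentration, numeric(1))
  expect_true(all(diff(cs) > 0))
  expect_error(estimateConcentration(e, 250000, sample,
                                     captureEfficiency = 0), "\\(0, 1\\]")
})

test_that("digital-regime check uses the expected molecule count", {
  r <- checkDigitalRegime(SampleSpec(1031, 40), 250000)
  expect_true(r$digital)
  expect_equal(r$ratio, 1031 * 40 * 0.6022 / 250000, tolerance = 1e-12)
  expect_false(checkDigitalRegime(SampleSpec(2062, 40), 250000)$digital)
  r0 <- checkDigitalRegime(SampleSpec(0, 40), 250000)
  expect_true(r0$digital)
  expect_identical(r0$ratio, 0)
})

test_that("multinomial loading reproduces the Poisson occupancy law", {
  # N molecules on M pillars at ratio 0.1: empirical occupancy histogram
  # matches the Poisson pmf within 3 sigma multinomial sampling error
  set.seed(99)
  M <- 250000; N <- 25000
  tab <- tabulate(sample.int(M, N, replace = TRUE), nbins = M)
  lam <- N / M
  for (k in 0:2) {
    p <- occupancyPmf(lam, k)
    expect_lt(abs(sum(tab == k) - M * p), 3 * sqrt(M * p * (1 - p)) + 1)
  }
})

test_that("Abbe spot size matches the instrument configuration", {
  expect_equal(abbeSpotSize(632.8, 0.90), 857.80, tolerance = 1e-5)
  expect_error(abbeSpotSize(0, 1), "positive")
})
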