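## Single-cell kinetic laws and their closed-form oracles.

test_that("growth rate is the exponential law with exact doubling", {
  p <- modelParams(0.463, 0.1, 39.519, 7.87e3, 7.61e-2, 1.74e4,
                   doublingTime = 16)
  expect_equal(growthRate(0, p), 0)
  expect_equal(growthRate(0.5, p), log(2) / 16 * 0.5, tolerance = 1e-12)
  ## closed-form check value
  expect_equal(growthRate(0.5, p), 0.02166085, tolerance = 1e-6)
  ## linearity
  x <- c(0.1, 0.25, 0.8)
  expect_equal(growthRate(2 * x, p), 2 * growthRate(x, p))
  ## integrating dx/dt = r1(x) over one doubling time doubles the size
  x0 <- 0.3
  sol <- x0 * exp(log(2) / 16 * 16)
  expect_equal(sol, 2 * x0)
  ## fine explicit Euler reproduces the doubling to O(dt)
  x <- x0
  h <- 1e-4
  for (i in seq_len(16 / h)) x <- x + growthRate(x, p) * h
  expect_equal(x, 2 * x0, tolerance = 1e-4)
  expect_error(growthRate(-1, p), "must be >= 0")
})

test_that("division hazard matches the Gaussian survivor form and its cap", {
  p <- modelParams(0.463, 0.1, 39.519, 7.87e3, 7.61e-2, 1.74e4,
                   doublingTime = 16)
  ## at the mitotic mean the survivor is 1/2: Gamma = 2 r1(mu) g(mu)
  expect_equal(divisionRate(p@mu, p),
               2 * growthRate(p@mu, p) * dnorm(p@mu, p@mu, p@sigma),
               tolerance = 1e-12)
  expect_equal(divisionRate(p@mu, p), 0.160, tolerance = 1e-3)
  ## far-left tail: vanishing hazard (4 sigma below the mitotic mean)
  expect_lt(divisionRate(0.05, p), 1e-5)
  ## numeric-quadrature oracle across a grid (survivor integrated over
  ## the upper tail to avoid cancellation), and monotonicity above mu
  xs <- seq(p@mu, p@mu + 3.5 * p@sigma, length.out = 40)
  oracle <- vapply(xs, function(x) {
    surv <- integrate(dnorm, x, Inf, mean = p@mu, sd = p@sigma,
                      rel.tol = 1e-12)$value
    growthRate(x, p) * dnorm(x, p@mu, p@sigma) / surv
  }, 0)
  expect_equal(divisionRate(xs, p), oracle, tolerance = 1e-4)
  expect_true(all(diff(divisionRate(xs, p)) >= 0))
  ## survivor underflow: capped large value, never NaN
  far <- divisionRate(c(5, 50), p)
  expect_true(all(is.finite(far)))
  expect_equal(far, c(1e4, 1e4))
  expect_error(divisionRate(0, p), "must be > 0")
})

test_that("partition fractions are symmetric beta with the closed-form moments", {
  set.seed(11)
  q <- 39.519
  f <- samplePartitionFraction(1e5, q)
  expect_true(all(f > 0 & f < 1))
  se <- sqrt(1 / (4 * (2 * q + 1)) / 1e5)
  expect_lt(abs(mean(f) - 0.5), 3 * se)
  expect_equal(var(f), 1 / (4 * (2 * q + 1)), tolerance = 0.02)
  expect_equal(1 / (4 * (2 * q + 1)), 3.1235e-3, tolerance = 1e-4)
  ## conservation of a symmetric split
  expect_equal(0.5 * 0.8 + (1 - 0.5) * 0.8, 0.8)
  ## asymmetric q still symmetric around 1/2
  set.seed(12)
  f2 <- samplePartitionFraction(1e5, 2)
  expect_lt(abs(mean(f2) - 0.5), 3 * sqrt(1 / (4 * 5) / 1e5))
  expect_error(samplePartitionFraction(10, -1), "positive")
  ## ModelParams dispatch
  set.seed(13)
  expect_length(samplePartitionFraction(5, refParams()), 5)
})

test_that("NANOG Euler-Maruyama step has the right fixed point and relaxation", {
  p0 <- noDivisionParams(delta = 0)
  fix <- p0@alpha / p0@d
  expect_equal(fix, 1.034e5, tolerance = 1e-3)
  expect_equal(nanogStep(fix, 0.01, p0), fix, tolerance = 1e-12)
  ## deterministic relaxation from 0 matches N(t) = (alpha/d)(1 - e^(-dt))
  N <- 0; h <- 0.01; Tend <- 120
  for (i in seq_len(Tend / h)) N <- nanogStep(N, h, p0)
  expect_equal(N, fix * (1 - exp(-p0@d * Tend)), tolerance = 1e-3)
  expect_error(nanogStep(1e4, -0.1, p0), "positive")
  expect_error(nanogStep(-5, 0.1, p0), ">= 0")
})

test_that("long-run NANOG fluctuations match the OU stationary law", {
  p <- noDivisionParams(delta = 1.74e4)
  sdTheory <- sqrt(p@delta^2 / (2 * p@d))
  expect_equal(sdTheory, 4.46e4, tolerance = 1e-3)
  ## ensemble of independent cells, burn past the OU relaxation time
  set.seed(21)
  n <- 3000
  N <- rep(p@alpha / p@d, n)
  h <- 0.01
  for (i in seq_len(80 / h)) N <- nanogStep(N, h, p)
  expect_equal(sd(N), sdTheory, tolerance = 0.05)
  expect_equal(mean(N), p@alpha / p@d, tolerance = 0.05)
})

test_that("parameter and config validity invariants are enforced", {
  expect_error(modelParams(1.2, 0.1, 39, 7e3, 0.07, 1e4, 10), "mu")
  expect_error(modelParams(0.5, -0.1, 39, 7e3, 0.07, 1e4, 10), "sigma")
  expect_error(modelParams(0.5, 0.1, 0, 7e3, 0.07, 1e4, 10), "q")
  expect_error(modelParams(0.5, 0.1, 39, 7e3, 0, 1e4, 10), "d")
  expect_error(modelParams(0.5, 0.1, 39, 7e3, 0.07, 1e4, 0), "doublingTime")
  expect_error(simulationConfig(k0 = 100, kmax = 50, tTotal = 1), "kmax")
  expect_error(simulationConfig(k0 = 10, kmax = 20, tTotal = 1, dt = 0),
               "dt")
  expect_error(populationSnapshot(data.frame(size = -1, nanog = 10)),
               "size")
  ## doubling-time calibration closed form
  expect_equal(calibrateDoublingTime(7.87e3, 7.61e-2, 5.37e4), 9.8382,
               tolerance = 1e-4)
  expect_error(calibrateDoublingTime(7.87e3, 7.61e-2, 2e5), "targetMean")
})
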