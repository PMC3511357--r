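## Engine-level properties of runSimulation.

test_that("zero-horizon runs return the initial snapshot only", {
  p <- refParams()
  cfg <- smallConfig(k0 = 10L, kmax = 20L, tTotal = 0, recordTimes = 0)
  set.seed(1)
  init <- initialPopulation(p, 10L)
  snaps <- runSimulation(p, cfg, init = init)
  expect_length(snaps, 1L)
  expect_equal(snapshotTime(snaps[[1]]), 0)
  expect_equal(cellData(snaps[[1]])$size, cellData(init)$size)
  expect_equal(snaps[[1]]@nDivisions, 0L)
})

test_that("fixed seeds give byte-identical snapshot sequences", {
  p <- refParams()
  cfg <- smallConfig(tTotal = 8, seed = 99L,
                     recordTimes = c(2, 4, 8))
  a <- runSimulation(p, cfg)
  b <- runSimulation(p, cfg)
  expect_identical(a, b)
  cfg2 <- smallConfig(tTotal = 8, seed = 100L, recordTimes = c(2, 4, 8))
  c <- runSimulation(p, cfg2)
  expect_false(identical(cellData(a[[3]]), cellData(c[[3]])))
})

test_that("population count is conserved exactly in the constant-number phase", {
  p <- refParams()
  cfg <- smallConfig(k0 = 100L, kmax = 150L, tTotal = 3 * p@doublingTime,
                     seed = 7L, recordTimes = c(1, 2, 3) * p@doublingTime)
  snaps <- runSimulation(p, cfg)
  ns <- vapply(snaps, function(s) nrow(cellData(s)), 0L)
  expect_equal(ns[2], 150L)
  expect_equal(ns[3], 150L)
  expect_true(all(ns <= 150L))
  ## divisions continue while the count stays flat
  expect_gt(snaps[[3]]@nDivisions, snaps[[2]]@nDivisions)
})

test_that("with division off and no noise, cells follow the analytic ODEs", {
  p <- noDivisionParams(delta = 0)
  set.seed(3)
  init <- populationSnapshot(data.frame(size = runif(20, 0.1, 0.25),
                                        nanog = runif(20, 1e4, 9e4)))
  Tend <- 6
  cfg <- smallConfig(k0 = 20L, kmax = 40L, tTotal = Tend, seed = 4L,
                     recordTimes = Tend)
  out <- cellData(runSimulation(p, cfg, init = init)[[1]])
  x0 <- cellData(init)$size
  N0 <- cellData(init)$nanog
  kg <- log(2) / p@doublingTime
  ## explicit Euler at dt = 0.01: cumulative relative error ~ n (k dt)^2 / 2
  expect_equal(out$size, x0 * exp(kg * Tend), tolerance = 5e-4)
  fix <- p@alpha / p@d
  expect_equal(out$nanog, fix + (N0 - fix) * exp(-p@d * Tend),
               tolerance = 1e-3)
  expect_equal(out$arrested, rep(FALSE, 20))
})

test_that("sampled quiescence intervals are exponential when the hazard is effectively frozen", {
  ## a large ensemble makes intervals far shorter than the growth
  ## timescale, so the total hazard is constant over each draw and the
  ## interval law collapses to Exp(Lambda)
  p <- refParams()
  snap <- snapshotOfSizes(rep(c(0.45, 0.5, 0.55), each = 200))
  lam <- totalHazard(snap, p)
  set.seed(61)
  us <- runif(1e4)
  Ts <- -log1p(-us) / lam  # closed form of the single-rectangle regime
  ## draws within one quadrature step match the closed form exactly;
  ## longer draws pick up the (hazard-increasing) growth correction
  short <- which(Ts[1:50] <= 0.01)
  TsOp <- vapply(us[short], function(u) sampleQuiescenceInterval(snap, p, u), 0)
  expect_equal(TsOp, Ts[short], tolerance = 1e-9)
  ks <- suppressWarnings(ks.test(Ts, "pexp", rate = lam))
  expect_gt(ks$p.value, 0.01)
})

test_that("the stationary size distribution is time-invariant", {
  p <- refParams()
  Td <- p@doublingTime
  cfg <- smallConfig(k0 = 2000L, kmax = 4000L, tTotal = 3 * Td, seed = 8L,
                     recordTimes = c(2, 3) * Td)
  snaps <- runSimulation(p, cfg)
  s1 <- cellData(snaps[[1]])$size
  s2 <- cellData(snaps[[2]])$size
  ks <- suppressWarnings(ks.test(s1, s2))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("blocked division freezes growth, raises mean NANOG, and ends cleanly", {
  p <- refParams()
  set.seed(9)
  init <- stationaryEnsemble(p, k0 = 500, kmax = 1000, seed = 10L)
  cfg <- smallConfig(k0 = 1000L, kmax = 1000L, tTotal = 16, seed = 11L,
                     scenario = "BLOCKED_DIVISION", recordTimes = c(8, 16))
  snaps <- runSimulation(p, cfg, init = init)
  final <- snaps[[2]]
  expect_gt(mean(cellData(final)$nanog), mean(cellData(init)$nanog))
  expect_equal(final@nDivisions, 0L)
  expect_gt(final@nArrested, 0L)
  expect_equal(nrow(cellData(final)), 1000L)
  ## arrested cells never grow after arrest: total size bounded by the
  ## all-growing bound
  expect_lt(sum(cellData(final)$size),
            sum(cellData(init)$size) * 2^(16 / p@doublingTime))
  ## a fully arrested population still advances its SDE to the horizon
  allArr <- populationSnapshot(data.frame(size = rep(0.4, 50),
                                          nanog = rep(5e4, 50),
                                          arrested = TRUE))
  cfg2 <- smallConfig(k0 = 50L, kmax = 50L, tTotal = 4, seed = 12L,
                      scenario = "BLOCKED_DIVISION", recordTimes = 4)
  out <- runSimulation(p, cfg2, init = allArr)[[1]]
  expect_equal(snapshotTime(out), 4)
  expect_false(any(cellData(out)$nanog == 5e4))
  expect_equal(cellData(out)$size, rep(0.4, 50))
})

test_that("dual-reporter runs carry two reporters with conserved splits", {
  p <- refParams()
  set.seed(13)
  init <- initialPopulation(p, 300L)
  cfg <- smallConfig(k0 = 300L, kmax = 600L, tTotal = 2 * p@doublingTime,
                     seed = 14L, scenario = "DUAL_REPORTER")
  out <- cellData(runSimulation(p, cfg, init = init)[[1]])
  expect_false(any(is.na(out$nanog2)))
  expect_true(all(out$nanog2 >= 0))
  ## the reporters decorrelate but stay positively related through the
  ## shared division history
  r <- cor(out$nanog, out$nanog2)
  expect_gt(r, 0)
  expect_lt(r, 0.99)
})

test_that("scenario NO_EXPRESSION_NOISE forces deterministic NANOG kinetics", {
  p <- refParams()
  set.seed(15)
  init <- initialPopulation(p, 200L)
  cfg <- smallConfig(k0 = 200L, kmax = 400L, tTotal = 2 * p@doublingTime,
                     seed = 16L, scenario = "NO_EXPRESSION_NOISE")
  out <- cellData(runSimulation(p, cfg, init = init)[[1]])
  ## spread far below the full-scenario spread: partitioning/age only
  expect_lt(coefficientOfVariation(out$nanog), 0.4)
  expect_gt(nrow(out), 200L)
})
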