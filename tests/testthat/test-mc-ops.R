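## Event-loop operations: hazard summation, quiescence-interval sampling,
## dividing-cell selection, advancing, and division bookkeeping.

test_that("total hazard sums per-cell hazards and is additive", {
  p <- refParams()
  one <- snapshotOfSizes(p@mu)
  expect_equal(totalHazard(one, p), divisionRate(p@mu, p))
  many <- snapshotOfSizes(rep(0.5, 100))
  expect_equal(totalHazard(many, p), 100 * divisionRate(0.5, p),
               tolerance = 1e-12)
  ## duplicating every cell doubles the total
  sizes <- c(0.3, 0.45, 0.6)
  expect_equal(totalHazard(snapshotOfSizes(c(sizes, sizes)), p),
               2 * totalHazard(snapshotOfSizes(sizes), p))
  arrestedAll <- populationSnapshot(
    data.frame(size = 0.5, nanog = 1e4, arrested = TRUE))
  expect_error(totalHazard(arrestedAll, p), "no division possible")
})

test_that("frozen-hazard quiescence intervals follow the exponential closed form", {
  ## growth disabled: Lambda is constant, T = -ln(1-u)/Lambda
  pFrozen <- modelParams(0.463, 0.1, 39.519, 7.87e3, 7.61e-2, 0,
                         doublingTime = Inf)
  snap <- snapshotOfSizes(rep(0.5, 7))
  lam <- totalHazard(snap, pFrozen)
  expect_equal(lam, 0)  # zero growth implies zero hazard in this form
  ## a constant unit hazard via a direct check of the inversion formula:
  ## use growing sizes but tiny interval so the frozen solution is exact
  p <- refParams()
  snapBig <- snapshotOfSizes(rep(0.5, 500))
  lam <- totalHazard(snapBig, p)
  for (u in c(0.1, 0.5, 0.9)) {
    Tfrozen <- -log1p(-u) / lam
    if (Tfrozen <= 0.01) {
      expect_equal(sampleQuiescenceInterval(snapBig, p, u), Tfrozen,
                   tolerance = 1e-10)
    }
  }
  ## u -> 0+ gives T -> 0
  expect_lt(sampleQuiescenceInterval(snapBig, p, 1e-12), 1e-12)
  ## monotone in u
  us <- c(0.05, 0.2, 0.5, 0.8, 0.99)
  Ts <- vapply(us, function(u) sampleQuiescenceInterval(snapBig, p, u), 0)
  expect_true(all(diff(Ts) > 0))
})

test_that("growth shortens the interval relative to the frozen solution", {
  p <- refParams()
  ## few cells above mu: hazard nondecreasing along growth
  snap <- snapshotOfSizes(c(0.5, 0.55, 0.6))
  lam0 <- totalHazard(snap, p)
  for (u in c(0.6, 0.9, 0.99)) {
    Tfrozen <- -log1p(-u) / lam0
    Tgrow <- sampleQuiescenceInterval(snap, p, u)
    expect_lte(Tgrow, Tfrozen + 1e-9)
  }
  ## numeric quadrature oracle on one configuration: survivor of the
  ## integrated hazard evaluated at the sampled T recovers u
  u <- 0.9
  T <- sampleQuiescenceInterval(snap, p, u, dt = 0.002)
  kg <- log(2) / p@doublingTime
  integ <- integrate(function(s) {
    vapply(s, function(si)
      sum(divisionRate(c(0.5, 0.55, 0.6) * exp(kg * si), p)), 0)
  }, 0, T, rel.tol = 1e-10)$value
  expect_equal(1 - exp(-integ), u, tolerance = 2e-3)
})

test_that("dividing-cell selection matches the hazard weights", {
  p <- refParams()
  single <- snapshotOfSizes(0.5)
  expect_equal(selectDividingCell(single, p, 0.37), 1L)
  ## two equal cells split 50/50
  two <- snapshotOfSizes(c(0.5, 0.5))
  set.seed(31)
  picks <- vapply(runif(1e4), function(u) selectDividingCell(two, p, u), 0L)
  expect_lt(abs(mean(picks == 1L) - 0.5), 3 * sqrt(0.25 / 1e4))
  ## hazards in ratio 1:2:7 by construction: invert sizes from hazards is
  ## awkward, so check the generic weighting with a synthetic snapshot of
  ## sizes whose hazards we measure, against multinomial expectation
  sizes <- c(0.42, 0.5, 0.6)
  haz <- divisionRate(sizes, p)
  w <- haz / sum(haz)
  snap <- snapshotOfSizes(sizes)
  set.seed(32)
  n <- 1e5
  picks <- vapply(runif(n), function(u) selectDividingCell(snap, p, u), 0L)
  obs <- tabulate(picks, 3)
  chi <- sum((obs - n * w)^2 / (n * w))
  expect_lt(chi, qchisq(0.99, df = 2))
  expect_error(selectDividingCell(
    populationSnapshot(data.frame(size = 0.1, nanog = 1, arrested = TRUE)),
    p, 0.5), "no division possible")
})

test_that("advancePopulation integrates growth and freezes arrested cells", {
  p <- refParams()
  snap <- populationSnapshot(data.frame(
    size = c(0.3, 0.4), nanog = c(5e4, 6e4), arrested = c(FALSE, TRUE)))
  same <- advancePopulation(snap, 0, p)
  expect_equal(cellData(same), cellData(snap))
  ## deterministic kinetics: growth factor 2^(interval/Td) for live cells
  p0 <- modelParams(p@mu, p@sigma, p@q, p@alpha, p@d, 0, p@doublingTime)
  adv <- advancePopulation(snap, p0@doublingTime, p0, dt = 0.005)
  cells <- cellData(adv)
  expect_equal(cells$size[1], 0.3 * 2, tolerance = 5e-3)   # Euler O(dt)
  expect_equal(cells$size[2], 0.4)                          # frozen
  ## NANOG relaxes toward alpha/d in both cells
  expect_gt(cells$nanog[1], 5e4)
  expect_gt(cells$nanog[2], 6e4)
  ## arrested cells still fluctuate when delta > 0
  set.seed(41)
  advN <- advancePopulation(snap, 1, p)
  expect_false(cellData(advN)$nanog[2] == 6e4)
  expect_equal(cellData(advN)$size[2], 0.4)
})

test_that("division conserves content and respects the ensemble cap", {
  p <- refParams()
  snap <- populationSnapshot(data.frame(size = c(0.8, 0.3),
                                        nanog = c(9e4, 4e4)))
  set.seed(51)
  after <- divideCell(snap, 1L, p, kmax = Inf)
  cells <- cellData(after)
  expect_equal(nrow(cells), 3L)
  expect_equal(cells$size[1] + cells$size[3], 0.8, tolerance = 1e-12)
  expect_equal(cells$nanog[1] + cells$nanog[3], 9e4, tolerance = 1e-9)
  expect_equal(after@nDivisions, 1L)
  ## at the cap the count stays constant
  set.seed(52)
  capped <- divideCell(snap, 1L, p, kmax = 2L)
  expect_equal(nrow(cellData(capped)), 2L)
  expect_error(divideCell(snap, 5L, p), "out of range")
  ## size and NANOG partition fractions are independent draws
  set.seed(53)
  fracs <- t(replicate(5000, {
    a <- divideCell(snap, 1L, p, kmax = Inf)
    c(cellData(a)$size[1] / 0.8, cellData(a)$nanog[1] / 9e4)
  }))
  expect_lt(abs(cor(fracs[, 1], fracs[, 2])), 0.05)
})
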