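## Simulation-based parameter estimation: least-squares discrepancy between
## binned model and data densities, minimized by Nelder-Mead with common
## random numbers (fixed seed per fit) so the optimizer sees a
## deterministic surface.

#' Bin a sample into a normalized density
#'
#' @param values numeric sample.
#' @param edges bin edges covering the sample (values outside are
#'   clamped to the outermost bins).
#' @param time time stamp carried by the result.
#' @return A [DensityGrid-class].
#' @export
binDensity <- function(values, edges, time = 0) {
  if (!length(values)) stop("empty sample")
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  densityGrid(edges, counts / (length(values) * diff(edges)), time = time)
}

#' Least-squares discrepancy between binned densities
#'
#' \eqn{Z = \sum_{timepoints} \sum_{bins} (F_{model} - F_{data})^2} over
#' identically binned densities, normalized per timepoint; zero iff the
#' binned densities coincide, and symmetric in its arguments.
#'
#' @param modelDensity a [DensityGrid-class] or list of them.
#' @param dataDensity a [DensityGrid-class] or list matching
#'   \code{modelDensity} bin for bin.
#' @return Nonnegative scalar.
#' @examples
#' e <- 0:2
#' objectiveZ(densityGrid(e, c(0.4, 0.6)), densityGrid(e, c(0.5, 0.5)))  # 0.02
#' @export
objectiveZ <- function(modelDensity, dataDensity) {
  if (is(modelDensity, "DensityGrid")) modelDensity <- list(modelDensity)
  if (is(dataDensity, "DensityGrid")) dataDensity <- list(dataDensity)
  if (length(modelDensity) != length(dataDensity))
    stop("mismatched number of timepoints")
  z <- 0
  for (i in seq_along(modelDensity)) {
    m <- modelDensity[[i]]; d <- dataDensity[[i]]
    if (length(m@edges) != length(d@edges) ||
        max(abs(m@edges - d@edges)) > 1e-9)
      stop("mismatched bins between model and data densities")
    z <- z + sum((m@density - d@density)^2)
  }
  z
}

## Shared machinery: penalized objective over a named parameter subset.
## Out-of-box proposals are projected to the feasible region for
## simulation and charged an additive quadratic penalty (no silent
## clamping: the penalty drives the simplex back inside).
.penalty <- function(violation) 1e6 * sum(violation^2)

## Nelder-Mead with one automatic restart from the found point: a fresh
## simplex recovers from the degenerate-simplex stalls the method is
## prone to in flat valleys.
.nmWithRestart <- function(par0, fn, maxit) {
  r1 <- optim(par0, fn, method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-6))
  r2 <- optim(r1$par, fn, method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-6))
  if (r2$value <= r1$value) r2 else r1
}

.boxViolation <- function(theta, lower, upper) {
  pmax(lower - theta, 0) + pmax(theta - upper, 0)
}

.projectBox <- function(theta, lower, upper, margin) {
  pmin(pmax(theta, lower + margin), upper - margin)
}

.sizeDensities <- function(tables, edges) {
  lapply(tables, function(tb) {
    binDensity(normalizeFsc(eventData(tb)$fsc), edges)
  })
}

## Average a simulated stationary density over three late snapshots: the
## profile is stationary there, so averaging only reduces the Monte Carlo
## noise of the objective surface.
.simulatedDensity <- function(par, what, edges, k0, kmax, horizon, dt,
                              seed, scenario = "FULL", scale = 1) {
  Td <- par@doublingTime
  cfg <- simulationConfig(k0 = k0, kmax = kmax, tTotal = horizon * Td,
                          dt = dt, seed = seed, scenario = scenario,
                          recordTimes = c(horizon - 1, horizon - 0.5,
                                          horizon) * Td)
  snaps <- runSimulation(par, cfg)
  dens <- vapply(snaps, function(s) {
    v <- cellData(s)[[what]] / scale
    binDensity(pmin(v, max(edges) - 1e-12), edges)@density
  }, numeric(length(edges) - 1L))
  densityGrid(edges, rowMeans(dens), renormalize = TRUE)
}

#' Fit the size-law parameters (mu, sigma, q) to size distributions
#'
#' Nelder-Mead minimization of [objectiveZ()] between the observed
#' stationary normalized-size densities and the stationary solution of
#' the size-structured PBE at candidate \eqn{(\mu, \sigma, q)}, holding
#' the remaining parameters fixed. The forward model is the
#' deterministic finite-difference solution
#' ([stationarySizeDistribution()]), which gives the simplex an exactly
#' reproducible objective surface (the role common random numbers play
#' for a stochastic forward model) at a fraction of the cost; the
#' finite-difference and Monte Carlo stationary densities agree to
#' within the solver's discretization error. Proposals outside the
#' constraint box \eqn{0 < \mu < 1, \sigma > 0, q > 0} incur an additive
#' penalty of \code{1e6 * violation^2} (no silent clamping).
#'
#' @param data an [EventTable-class] or list of them; the \code{fsc}
#'   column is converted to normalized sizes.
#' @param start a [ModelParams-class] giving the starting point and the
#'   fixed non-size parameters (NANOG kinetics, doubling time).
#' @param nBins number of equal-width density bins on \[0, 1.2\].
#' @param fdNx finite-difference grid cells per objective evaluation
#'   (a multiple of \code{nBins}).
#' @param fdTol stationarity tolerance of each forward solve.
#' @param maxit Nelder-Mead iteration budget.
#' @return A [FitResult-class].
#' @export
fitSizeParams <- function(data, start = hescParams(), nBins = 64L,
                          fdNx = 3L * nBins, fdTol = 2e-4, maxit = 200L) {
  if (is(data, "EventTable")) data <- list(data)
  stopifnot(length(data) >= 1L, fdNx %% nBins == 0L)
  edges <- seq(0, 1.2, length.out = nBins + 1L)
  dataDens <- .sizeDensities(data, edges)
  agg <- as.integer(fdNx / nBins)
  lower <- c(mu = 0, sigma = 0, q = 0)
  upper <- c(mu = 1, sigma = Inf, q = Inf)
  margin <- c(mu = 1e-2, sigma = 5e-3, q = 0.5)
  trace <- numeric(0)
  evalN <- 0L

  obj <- function(theta) {
    evalN <<- evalN + 1L
    viol <- .boxViolation(theta, lower, upper)
    th <- .projectBox(theta, lower, upper, margin)
    par <- modelParams(th[1], th[2], th[3], alpha = 0, d = start@d,
                      delta = 0, doublingTime = start@doublingTime)
    z <- tryCatch({
      fd <- stationarySizeDistribution(par, nx = fdNx, tol = fdTol)
      modelDens <- densityGrid(
        edges, colSums(matrix(fd@density, nrow = agg)) / agg,
        renormalize = TRUE)
      objectiveZ(rep(list(modelDens), length(dataDens)), dataDens)
    }, error = function(e) 1e4)  # unresolvable corner of the box
    z <- z + .penalty(viol)
    trace <<- c(trace, z)
    z
  }

  res <- .nmWithRestart(c(start@mu, start@sigma, start@q), obj, maxit)
  th <- .projectBox(res$par, lower, upper, margin)
  fitted <- modelParams(th[1], th[2], th[3], start@alpha, start@d,
                        start@delta, start@doublingTime)
  new("FitResult", params = fitted, objectiveValue = res$value,
      nEvaluations = evalN, converged = res$convergence == 0L,
      trace = data.frame(evaluation = seq_along(trace), objective = trace))
}

#' Fit the NANOG kinetic parameters (alpha, d, delta)
#'
#' Second stage of the two-step estimation: with the size-law parameters
#' fixed, Nelder-Mead over \eqn{(\alpha, d, \delta)} against the observed
#' NANOG marginal densities (molecules, after MESF calibration), using
#' the same common-random-numbers machinery as [fitSizeParams()].
#' The doubling time is held fixed throughout (it is not identifiable
#' from snapshot shapes alone; it is set by the stationary-mean
#' calibration, see [calibrateDoublingTime()]).
#'
#' @param data numeric vector(s) of per-cell NANOG molecule counts (one
#'   vector per timepoint), or EventTable(s) with a \code{nanog} channel
#'   already in molecules.
#' @param sizeParams a [ModelParams-class] carrying the fixed size law
#'   and the starting NANOG kinetics.
#' @param nBins,k0,kmax,horizonDoublings,dt,seed,maxit as in
#'   [fitSizeParams()].
#' @return A [FitResult-class].
#' @export
fitNanogParams <- function(data, sizeParams = hescParams(), nBins = 64L,
                           k0 = 1000, kmax = 2000, horizonDoublings = 4,
                           dt = 0.01, seed = 1L, maxit = 200L) {
  asVec <- function(d) {
    if (is(d, "EventTable")) {
      if (is.null(eventData(d)$nanog)) stop("EventTable lacks a 'nanog' channel")
      eventData(d)$nanog
    } else as.numeric(d)
  }
  if (is(data, "EventTable") || is.numeric(data)) data <- list(data)
  samples <- lapply(data, asVec)
  hi <- 1.2 * max(vapply(samples, max, 0))
  ## bin on the normalized axis N / hi so the density values (and hence
  ## the objective) are O(1) regardless of the molecule scale
  edges <- seq(0, 1, length.out = nBins + 1L)
  dataDens <- lapply(samples, function(s) binDensity(s / hi, edges))
  lower <- c(alpha = 0, d = 0, delta = 0)
  upper <- c(alpha = Inf, d = Inf, delta = Inf)
  margin <- c(alpha = 0, d = 1e-6, delta = 0)
  trace <- numeric(0)
  evalN <- 0L

  obj <- function(theta) {
    evalN <<- evalN + 1L
    viol <- .boxViolation(theta, lower, upper)
    th <- .projectBox(theta, lower, upper, margin)
    par <- modelParams(sizeParams@mu, sizeParams@sigma, sizeParams@q,
                      th[1], th[2], th[3], sizeParams@doublingTime)
    modelDens <- .simulatedDensity(par, "nanog", edges, k0, kmax,
                                   horizonDoublings, dt, seed, scale = hi)
    z <- objectiveZ(rep(list(modelDens), length(dataDens)), dataDens) +
      .penalty(viol / c(1e3, 1e-2, 1e3))  # scale-aware violations
    trace <<- c(trace, z)
    z
  }

  ## optimize on a scaled parameterization so the simplex steps are
  ## commensurate across the three orders-of-magnitude-apart parameters
  scale <- c(sizeParams@alpha, sizeParams@d, max(sizeParams@delta, 1e3))
  res <- .nmWithRestart(c(1, 1, sizeParams@delta / scale[3]),
                        function(s) obj(s * scale), maxit)
  th <- .projectBox(res$par * scale, lower, upper, margin)
  fitted <- modelParams(sizeParams@mu, sizeParams@sigma, sizeParams@q,
                        th[1], th[2], th[3], sizeParams@doublingTime)
  new("FitResult", params = fitted, objectiveValue = res$value,
      nEvaluations = evalN, converged = res$convergence == 0L,
      trace = data.frame(evaluation = seq_along(trace), objective = trace))
}
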