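## Population-level simulation: initialization and the Monte Carlo driver.

.scenarioCode <- function(scenario) {
  match(scenario, .SCENARIOS) - 1L
}

.dEff <- function(params) {
  params@d + if (is.finite(params@doublingTime)) log(2) / params@doublingTime else 0
}

#' Default stationary size density shipped with the package
#'
#' Reads the packaged table of the stationary normalized-size density at
#' the reference hESC parameters, produced by the package's own
#' finite-difference PBE solver (see the file header of
#' \code{inst/extdata/stationary_size_density_synthetic.tsv}; the data are
#' synthetic, no experimental sizes are shipped).
#'
#' @return A \code{data.frame} with columns \code{x} and \code{density}.
#' @keywords internal
.defaultSizeDensity <- function() {
  path <- system.file("extdata", "stationary_size_density_synthetic.tsv",
                      package = "stempbe", mustWork = TRUE)
  read.delim(path, comment.char = "#")
}

#' Sample sizes from a tabulated density by inverse-CDF interpolation
#' @noRd
.sampleFromDensity <- function(n, x, density) {
  w <- diff(x)
  mids <- cumsum(c(0, density[-length(density)] * w))
  cdf <- mids / max(mids)
  keep <- !duplicated(cdf)   # flat (zero-density) stretches map to their left edge
  u <- runif(n)
  approx(cdf[keep], x[seq_along(cdf)][keep], xout = u, rule = 2)$y
}

#' Draw an initial cell ensemble
#'
#' Sizes default to the stationary size distribution of the reference
#' model (inverse-CDF sampling from the packaged density table); NANOG is
#' initialized at its Ornstein-Uhlenbeck stationary law with the dilution-
#' corrected degradation rate \eqn{d_{eff} = d + \ln 2 / T_d} (mean
#' \eqn{\alpha / d_{eff}}, st.dev. \eqn{\delta / \sqrt{2 d_{eff}}},
#' reflected at 0). Simulations are typically burned in for two doubling
#' times before metrics are recorded (see [stationaryEnsemble()]).
#'
#' @param params a [ModelParams-class].
#' @param n number of cells.
#' @param sizes optional numeric vector of initial sizes (recycled or
#'   sampled from if shorter than \code{n}); alternatively an
#'   [EventTable-class] whose \code{fsc} channel is converted through
#'   [normalizeFsc()].
#' @return A [PopulationSnapshot-class] at time 0.
#' @examples
#' set.seed(1)
#' initialPopulation(hescParams(), 100)
#' @export
initialPopulation <- function(params, n, sizes = NULL) {
  stopifnot(is(params, "ModelParams"), n >= 1)
  if (is.null(sizes)) {
    dens <- .defaultSizeDensity()
    sizes <- .sampleFromDensity(n, dens$x, dens$density)
  } else {
    if (is(sizes, "EventTable")) sizes <- normalizeFsc(eventData(sizes)$fsc)
    sizes <- if (length(sizes) == n) sizes else sample(sizes, n, replace = TRUE)
  }
  sizes <- pmax(sizes, 1e-6)
  de <- .dEff(params)
  nanog <- rnorm(n, params@alpha / de,
                 if (params@delta > 0) params@delta / sqrt(2 * de) else 0)
  nanog <- abs(nanog)
  populationSnapshot(data.frame(size = sizes, nanog = nanog), time = 0)
}

#' Run the stochastic PBE Monte Carlo simulation
#'
#' Event loop of the constant-volume/constant-number Monte Carlo solver:
#' sample an interval of quiescence from the survivor function of the
#' summed division hazard (Newton-Raphson on the growth-coupled hazard
#' integral), advance every cell over the interval (explicit Euler for
#' size, Euler-Maruyama for NANOG), select the dividing cell with
#' probability proportional to its hazard, and partition it into two
#' daughters by independent Beta(q, q) draws. Below \code{kmax} both
#' daughters join the ensemble; at \code{kmax} the second daughter
#' replaces a uniformly chosen other cell, keeping the count constant.
#'
#' Scenarios: \code{"FULL"} enables everything; \code{"NO_EXPRESSION_NOISE"}
#' forces \code{delta = 0} while division stays on;
#' \code{"BLOCKED_DIVISION"} moves a cell whose division event fires into
#' an arrested pool (no daughters, size frozen, NANOG SDE continues);
#' \code{"DUAL_REPORTER"} carries two NANOG reporters sharing
#' \code{alpha}, \code{d}, \code{delta} and \code{q}, each with its own
#' SDE realization and its own partition draw.
#'
#' @param params a [ModelParams-class].
#' @param config a [SimulationConfig-class].
#' @param init optional initial [PopulationSnapshot-class]; defaults to
#'   [initialPopulation()] with \code{config@k0} cells. In the
#'   dual-reporter scenario a missing second reporter is initialized equal
#'   to the first.
#' @return A list of [PopulationSnapshot-class] objects, one per
#'   \code{config@recordTimes} entry. Identical seeds yield identical
#'   output.
#' @examples
#' p <- hescParams()
#' cfg <- simulationConfig(k0 = 50, kmax = 100, tTotal = 5, seed = 1)
#' snaps <- runSimulation(p, cfg)
#' snaps[[1]]
#' @export
runSimulation <- function(params, config, init = NULL) {
  stopifnot(is(params, "ModelParams"), is(config, "SimulationConfig"))
  validObject(params); validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  if (is.null(init)) init <- initialPopulation(params, config@k0)
  stopifnot(is(init, "PopulationSnapshot"))
  cells <- cellData(init)
  if (nrow(cells) > config@kmax)
    stop("initial ensemble larger than 'kmax'")
  nanog2 <- cells$nanog2
  if (config@scenario == "DUAL_REPORTER" && all(is.na(nanog2)))
    nanog2 <- cells$nanog
  nanog2[is.na(nanog2)] <- 0
  raw <- .mc_engine_run(
    as.numeric(cells$size), as.numeric(cells$nanog), as.numeric(nanog2),
    as.logical(cells$arrested),
    as.list(paramValues(params)), .scenarioCode(config@scenario),
    config@kmax, config@tTotal, config@dt, config@recordTimes
  )
  lapply(raw, function(s) {
    populationSnapshot(
      data.frame(size = s$size, nanog = s$nanog, nanog2 = s$nanog2,
                 arrested = s$arrested),
      time = s$time, nDivisions = as.integer(s$nDivisions),
      nArrested = as.integer(s$nArrested)
    )
  })
}

#' Burn a population in to stationarity under the full model
#'
#' Runs the \code{FULL} scenario from [initialPopulation()] for
#' \code{burnInDoublings} doubling times and returns the final snapshot
#' (divisions/arrest counters reset, time reset to 0), to be used as the
#' initial ensemble of scenario comparisons. Two doubling times suffice
#' for the reference model because inherited fluctuations decay by more
#' than an order of magnitude per division cycle.
#'
#' @param params a [ModelParams-class].
#' @param k0 initial ensemble size.
#' @param kmax ensemble cap.
#' @param burnInDoublings burn-in length in units of the doubling time.
#' @param dt integration step (hr).
#' @param seed integer seed, or \code{NA}.
#' @return A [PopulationSnapshot-class] at time 0.
#' @export
stationaryEnsemble <- function(params, k0 = 5000, kmax = 10000,
                               burnInDoublings = 2, dt = 0.01, seed = NA) {
  cfg <- simulationConfig(
    k0 = k0, kmax = kmax,
    tTotal = burnInDoublings * params@doublingTime, dt = dt, seed = seed,
    scenario = "FULL"
  )
  snap <- runSimulation(params, cfg)[[length(cfg@recordTimes)]]
  populationSnapshot(cellData(snap), time = 0)
}

#' Summary statistics of a population snapshot
#'
#' @param snapshot a [PopulationSnapshot-class].
#' @param reference optional reference NANOG sample for LN/HN gating (see
#'   [gateLnHn()]).
#' @return Named list with \code{n}, \code{meanSize}, \code{meanNanog},
#'   \code{cvNanog}, \code{totalNoise}, \code{corrSizeNanog},
#'   \code{nDivisions}, \code{nArrested}; adds \code{lnFraction} and
#'   \code{hnFraction} when a reference is given, and the dual-reporter
#'   squared-noise triple when the second reporter is present.
#' @export
snapshotSummary <- function(snapshot, reference = NULL) {
  cells <- cellData(snapshot)
  out <- list(
    time = snapshotTime(snapshot),
    n = nrow(cells),
    meanSize = mean(cells$size),
    meanNanog = mean(cells$nanog),
    cvNanog = coefficientOfVariation(cells$nanog),
    totalNoise = totalNoise(cells$nanog),
    corrSizeNanog = sizeNanogCorrelation(cells[c("size", "nanog")]),
    nDivisions = snapshot@nDivisions,
    nArrested = snapshot@nArrested
  )
  if (!is.null(reference)) {
    gates <- gateLnHn(reference, cells$nanog)
    out$lnFraction <- gates[["lnFraction"]]
    out$hnFraction <- gates[["hnFraction"]]
  }
  if (!all(is.na(cells$nanog2))) {
    dec <- dualReporterDecomposition(cells[c("nanog", "nanog2")])
    out <- c(out, as.list(noiseValues(dec)))
  }
  out
}
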