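## User-facing constructors, accessors and show methods.

#' Create a ModelParams object
#'
#' @param mu mean mitotic size (normalized units, in (0, 1)).
#' @param sigma st.dev. of mitotic size.
#' @param q symmetric beta partition shape parameter (> 0).
#' @param alpha NANOG production rate (molecules/hr).
#' @param d NANOG first-order degradation rate (1/hr).
#' @param delta NANOG white-noise amplitude (molecules/hr).
#' @param doublingTime single-cell size doubling time (hr).
#' @return A validated [ModelParams-class] object.
#' @examples
#' modelParams(mu = 0.5, sigma = 0.08, q = 20,
#'             alpha = 8000, d = 0.08, delta = 15000, doublingTime = 12)
#' @export
modelParams <- function(mu, sigma, q, alpha, d, delta, doublingTime) {
  new("ModelParams",
    mu = as.numeric(mu), sigma = as.numeric(sigma), q = as.numeric(q),
    alpha = as.numeric(alpha), d = as.numeric(d), delta = as.numeric(delta),
    doublingTime = as.numeric(doublingTime)
  )
}

#' Reference hESC parameter set
#'
#' The parameter values estimated from self-renewing H9 hESC flow-cytometry
#' distributions (mitotic size law, partitioning shape, NANOG kinetics),
#' with the doubling time calibrated so that the stationary population mean
#' of NANOG equals \code{targetMeanNanog} molecules/cell (see
#' [calibrateDoublingTime()]).
#'
#' @param targetMeanNanog stationary mean NANOG (molecules/cell) used to
#'   calibrate the doubling time; default 5.37e4.
#' @return A [ModelParams-class] object.
#' @examples
#' hescParams()
#' @export
hescParams <- function(targetMeanNanog = 5.37e4) {
  alpha <- 7.87e3
  d <- 7.61e-2
  modelParams(
    mu = 0.463, sigma = 0.100, q = 39.519,
    alpha = alpha, d = d, delta = 1.74e4,
    doublingTime = calibrateDoublingTime(alpha, d, targetMeanNanog)
  )
}

#' Calibrate the doubling time from the stationary mean NANOG level
#'
#' In a balanced exponentially growing population the per-cell mean NANOG
#' obeys \eqn{d\bar N/dt = \alpha - (d + \ln 2 / T_d)\,\bar N}: production
#' minus degradation minus dilution at the population growth rate (division
#' conserves total NANOG while doubling cell number every \eqn{T_d}). The
#' stationary mean is therefore \eqn{\alpha / (d + \ln 2 / T_d)}, which is
#' inverted for \eqn{T_d}.
#'
#' @param alpha NANOG production rate (molecules/hr).
#' @param d NANOG degradation rate (1/hr).
#' @param targetMean stationary mean NANOG (molecules/cell).
#' @return Doubling time (hr).
#' @examples
#' calibrateDoublingTime(7.87e3, 7.61e-2, 5.37e4)  # ~9.84 hr
#' @export
calibrateDoublingTime <- function(alpha, d, targetMean) {
  stopifnot(alpha > 0, d > 0, targetMean > 0)
  k <- alpha / targetMean - d
  if (k <= 0)
    stop("'targetMean' >= alpha/d: no positive doubling time yields this mean")
  log(2) / k
}

#' Create a SimulationConfig object
#'
#' @param k0 initial ensemble size (cells).
#' @param kmax ensemble cap (cells).
#' @param tTotal simulation horizon (hr).
#' @param dt SDE/growth integration step (hr).
#' @param seed integer random seed, or \code{NA} to leave the RNG state
#'   untouched.
#' @param scenario simulated scenario; see [SimulationConfig-class].
#' @param recordTimes snapshot times (hr); defaults to \code{tTotal} only.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' simulationConfig(k0 = 100, kmax = 200, tTotal = 10, seed = 1)
#' @export
simulationConfig <- function(k0, kmax, tTotal, dt = 0.01, seed = NA,
                             scenario = "FULL", recordTimes = tTotal) {
  new("SimulationConfig",
    k0 = as.integer(k0), kmax = as.integer(kmax),
    tTotal = as.numeric(tTotal), dt = as.numeric(dt),
    seed = as.integer(seed), scenario = match.arg(scenario, .SCENARIOS),
    recordTimes = as.numeric(recordTimes)
  )
}

#' Create a PopulationSnapshot object
#'
#' @param cells \code{data.frame} with at least a \code{size} and a
#'   \code{nanog} column; \code{nanog2} and \code{arrested} are filled in
#'   when absent.
#' @param time snapshot time (hr).
#' @param nDivisions cumulative division count.
#' @param nArrested blocked-pool size; defaults to the number of arrested
#'   cells.
#' @return A validated [PopulationSnapshot-class] object.
#' @examples
#' populationSnapshot(data.frame(size = c(0.3, 0.5), nanog = c(4e4, 6e4)))
#' @export
populationSnapshot <- function(cells, time = 0, nDivisions = 0L,
                               nArrested = NULL) {
  cells <- as.data.frame(cells)
  if (is.null(cells$nanog2)) cells$nanog2 <- NA_real_
  if (is.null(cells$arrested)) cells$arrested <- FALSE
  cells <- cells[c("size", "nanog", "nanog2", "arrested")]
  if (is.null(nArrested)) nArrested <- sum(cells$arrested)
  new("PopulationSnapshot",
    time = as.numeric(time), cells = cells,
    nDivisions = as.integer(nDivisions), nArrested = as.integer(nArrested)
  )
}

#' Create a DensityGrid object
#'
#' @param edges ordered bin edges.
#' @param density per-bin density values; renormalized to integrate to 1
#'   when \code{renormalize = TRUE}.
#' @param time time stamp (hr).
#' @param renormalize divide by the current integral before validation.
#' @return A validated [DensityGrid-class] object.
#' @export
densityGrid <- function(edges, density, time = 0, renormalize = FALSE) {
  edges <- as.numeric(edges)
  density <- as.numeric(density)
  if (renormalize) {
    mass <- sum(density * diff(edges))
    if (mass <= 0) stop("cannot renormalize a density with zero mass")
    density <- density / mass
  }
  new("DensityGrid", edges = edges, density = density, time = as.numeric(time))
}

#' Create an EventTable object
#'
#' @param events \code{data.frame} with an \code{fsc} column plus named
#'   fluorescence channels.
#' @param channels character vector naming the fluorescence columns; by
#'   default every non-\code{fsc} numeric column.
#' @param label optional acquisition label.
#' @param day optional time point (days after plating).
#' @return A validated [EventTable-class] object.
#' @examples
#' eventTable(data.frame(fsc = c(400, 500), nanog_au = c(120, 250)))
#' @export
eventTable <- function(events, channels = NULL, label = NULL, day = NULL) {
  events <- as.data.frame(events)
  if (is.null(channels)) {
    channels <- setdiff(names(events)[vapply(events, is.numeric, TRUE)], "fsc")
  }
  meta <- list(channels = channels)
  if (!is.null(label)) meta$label <- label
  if (!is.null(day)) meta$day <- day
  new("EventTable", events = events, metadata = meta)
}

#' Create a SyntheticSpec object
#'
#' @param params ground-truth [ModelParams-class]; defaults to
#'   [hescParams()].
#' @param nEvents number of cell events to generate.
#' @param noiseCvMeasurement multiplicative lognormal measurement noise CV
#'   per channel (flow-standard); default 0.10.
#' @param beadLevels number of calibration bead populations.
#' @param seed integer random seed.
#' @return A validated [SyntheticSpec-class] object.
#' @export
syntheticSpec <- function(params = hescParams(), nEvents = 10000L,
                          noiseCvMeasurement = 0.10, beadLevels = 6L,
                          seed = 1L) {
  new("SyntheticSpec",
    params = params, nEvents = as.integer(nEvents),
    noiseCvMeasurement = as.numeric(noiseCvMeasurement),
    beadLevels = as.integer(beadLevels), seed = as.integer(seed)
  )
}

## ---- accessors -------------------------------------------------------------

#' @describeIn populationSnapshot Per-cell state data frame of a snapshot.
#' @param x a [PopulationSnapshot-class].
#' @export
cellData <- function(x) {
  stopifnot(is(x, "PopulationSnapshot"))
  x@cells
}

#' @describeIn populationSnapshot Snapshot time (hr).
#' @export
snapshotTime <- function(x) {
  stopifnot(is(x, "PopulationSnapshot"))
  x@time
}

#' @describeIn eventTable Event data frame of an [EventTable-class].
#' @param x an [EventTable-class].
#' @export
eventData <- function(x) {
  stopifnot(is(x, "EventTable"))
  x@events
}

#' @describeIn eventTable Declared fluorescence channel names.
#' @export
channelNames <- function(x) {
  stopifnot(is(x, "EventTable"))
  x@metadata$channels
}

#' Named numeric vector of kinetic parameter values
#'
#' @param params a [ModelParams-class].
#' @return Named numeric vector with elements \code{mu}, \code{sigma},
#'   \code{q}, \code{alpha}, \code{d}, \code{delta}, \code{doublingTime}.
#' @export
paramValues <- function(params) {
  stopifnot(is(params, "ModelParams"))
  c(mu = params@mu, sigma = params@sigma, q = params@q,
    alpha = params@alpha, d = params@d, delta = params@delta,
    doublingTime = params@doublingTime)
}

#' @describeIn dualReporterDecomposition Extract the squared-noise triple
#'   as a named numeric vector.
#' @param x a [NoiseDecomposition-class].
#' @export
noiseValues <- function(x) {
  stopifnot(is(x, "NoiseDecomposition"))
  c(etaTotSq = x@etaTotSq, etaIntSq = x@etaIntSq, etaExtSq = x@etaExtSq)
}

#' @describeIn fitSizeParams Extract fitted parameters from a
#'   [FitResult-class].
#' @param fit a [FitResult-class].
#' @export
fittedParams <- function(fit) {
  stopifnot(is(fit, "FitResult"))
  fit@params
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "ModelParams", function(object) {
  v <- paramValues(object)
  cat("ModelParams\n")
  cat(sprintf("  mitotic size: mu = %.4g, sigma = %.4g; partition q = %.4g\n",
              v["mu"], v["sigma"], v["q"]))
  cat(sprintf("  NANOG: alpha = %.4g molecules/hr, d = %.4g /hr, delta = %.4g molecules/hr\n",
              v["alpha"], v["d"], v["delta"]))
  cat(sprintf("  doubling time: %.4g hr\n", v["doublingTime"]))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %s, k0 = %d, kmax = %d, tTotal = %.4g hr, dt = %.4g hr\n",
              object@scenario, object@k0, object@kmax, object@tTotal, object@dt))
  cat(sprintf("  seed: %s; %d record time(s)\n",
              ifelse(is.na(object@seed), "<current RNG>", object@seed),
              length(object@recordTimes)))
})

setMethod("show", "PopulationSnapshot", function(object) {
  cat(sprintf("PopulationSnapshot at t = %.4g hr: %d cells (%d arrested), %d divisions\n",
              object@time, nrow(object@cells), object@nArrested, object@nDivisions))
  if (nrow(object@cells)) {
    cat(sprintf("  mean size %.4g, mean NANOG %.4g molecules\n",
                mean(object@cells$size), mean(object@cells$nanog)))
  }
})

setMethod("show", "EventTable", function(object) {
  cat(sprintf("EventTable: %d events, channels: %s\n", nrow(object@events),
              paste(object@metadata$channels, collapse = ", ")))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve: %d bead levels, log10(molecules) = %.4g + %.4g * log10(AU)\n",
              nrow(object@beads), object@intercept, object@slope))
})

setMethod("show", "NoiseDecomposition", function(object) {
  cat(sprintf("NoiseDecomposition: eta_tot^2 = %.4g (intrinsic %.4g, extrinsic %.4g; extrinsic share %.1f%%)\n",
              object@etaTotSq, object@etaIntSq, object@etaExtSq,
              100 * object@etaExtSq / object@etaTotSq))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: objective = %.6g after %d evaluations (%s)\n",
              object@objectiveValue, object@nEvaluations,
              if (object@converged) "converged" else "not converged"))
  show(object@params)
})

setMethod("show", "DensityGrid", function(object) {
  cat(sprintf("DensityGrid: %d bins on [%.4g, %.4g] at t = %.4g hr\n",
              length(object@density), min(object@edges), max(object@edges),
              object@time))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d events, measurement CV %.3g, %d bead levels, seed %d\n",
              object@nEvents, object@noiseCvMeasurement, object@beadLevels,
              object@seed))
})
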