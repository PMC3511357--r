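## S4 class definitions and validity methods.

#' Single-cell kinetic and partitioning parameters
#'
#' Container for the kinetic laws governing one hESC: the Gaussian law of
#' mitotic sizes (mean \code{mu}, st.dev. \code{sigma}, normalized size
#' units on \[0, 1\]), the symmetric Beta(q, q) partitioning shape
#' \code{q}, the NANOG production rate \code{alpha} (molecules/hr),
#' first-order degradation rate \code{d} (1/hr), white-noise amplitude
#' \code{delta} (molecules/hr), and the single-cell size doubling time
#' \code{doublingTime} (hr).
#'
#' @slot mu mean mitotic size, in (0, 1).
#' @slot sigma st.dev. of mitotic size, > 0.
#' @slot q beta partition shape parameter, > 0.
#' @slot alpha NANOG production rate (molecules/hr), >= 0.
#' @slot d NANOG degradation rate (1/hr), > 0.
#' @slot delta NANOG white-noise amplitude (molecules/hr), >= 0.
#' @slot doublingTime single-cell size doubling time (hr), > 0 (may be
#'   \code{Inf} to freeze growth).
#'
#' @seealso [modelParams()], [hescParams()]
#' @export
setClass("ModelParams",
  representation(
    mu = "numeric", sigma = "numeric", q = "numeric",
    alpha = "numeric", d = "numeric", delta = "numeric",
    doublingTime = "numeric"
  )
)

setValidity("ModelParams", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x) || identical(x, Inf)
  for (s in c("mu", "sigma", "q", "alpha", "d", "delta", "doublingTime")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v)) msg <- c(msg, sprintf("'%s' must be a single non-missing number", s))
  }
  if (length(msg)) return(msg)
  if (!(object@mu > 0 && object@mu < 1)) msg <- c(msg, "'mu' must lie in (0, 1)")
  if (object@sigma <= 0) msg <- c(msg, "'sigma' must be > 0")
  if (object@q <= 0) msg <- c(msg, "'q' must be > 0")
  if (object@alpha < 0) msg <- c(msg, "'alpha' must be >= 0")
  if (object@d <= 0) msg <- c(msg, "'d' must be > 0")
  if (object@delta < 0) msg <- c(msg, "'delta' must be >= 0")
  if (object@doublingTime <= 0) msg <- c(msg, "'doublingTime' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Monte Carlo simulation bookkeeping
#'
#' Configuration of a population-level Monte Carlo run: initial ensemble
#' size \code{k0}, constant-number cap \code{kmax}, horizon \code{tTotal}
#' (hr), SDE/growth integration step \code{dt} (hr), random seed,
#' simulated scenario, and the times at which population snapshots are
#' recorded.
#'
#' @slot k0 initial ensemble size (cells).
#' @slot kmax ensemble cap (cells); once reached the solver switches from
#'   constant-volume to constant-number bookkeeping.
#' @slot tTotal simulation horizon (hr).
#' @slot dt integration step (hr); event intervals are sub-stepped so no
#'   step exceeds \code{dt}.
#' @slot seed integer random seed, or \code{NA} to use the current RNG
#'   state.
#' @slot scenario one of \code{"FULL"}, \code{"NO_EXPRESSION_NOISE"},
#'   \code{"BLOCKED_DIVISION"}, \code{"DUAL_REPORTER"}.
#' @slot recordTimes times (hr) at which snapshots are saved.
#'
#' @seealso [simulationConfig()], [runSimulation()]
#' @export
setClass("SimulationConfig",
  representation(
    k0 = "integer", kmax = "integer", tTotal = "numeric", dt = "numeric",
    seed = "integer", scenario = "character", recordTimes = "numeric"
  )
)

.SCENARIOS <- c("FULL", "NO_EXPRESSION_NOISE", "BLOCKED_DIVISION", "DUAL_REPORTER")

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@k0 < 1L) msg <- c(msg, "'k0' must be >= 1")
  if (object@kmax < object@k0) msg <- c(msg, "'kmax' must be >= 'k0'")
  if (!(object@tTotal >= 0)) msg <- c(msg, "'tTotal' must be >= 0")
  if (!(object@dt > 0)) msg <- c(msg, "'dt' must be > 0")
  if (!object@scenario %in% .SCENARIOS)
    msg <- c(msg, paste("'scenario' must be one of", paste(.SCENARIOS, collapse = ", ")))
  if (any(object@recordTimes < 0) || is.unsorted(object@recordTimes, strictly = TRUE))
    msg <- c(msg, "'recordTimes' must be strictly increasing and >= 0")
  if (length(object@recordTimes) && max(object@recordTimes) > object@tTotal)
    msg <- c(msg, "'recordTimes' must not exceed 'tTotal'")
  if (length(msg)) msg else TRUE
})

#' A recorded state of the simulated cell ensemble
#'
#' One time point of a Monte Carlo run: per-cell states plus cumulative
#' event counters. The \code{cells} data frame has columns \code{size}
#' (normalized), \code{nanog} (molecules), \code{nanog2} (molecules,
#' \code{NA} outside the dual-reporter scenario) and \code{arrested}
#' (membership in the blocked-division pool).
#'
#' @slot time snapshot time (hr).
#' @slot cells per-cell state \code{data.frame}.
#' @slot nDivisions cumulative division count at \code{time}.
#' @slot nArrested number of cells in the blocked-division pool.
#'
#' @seealso [populationSnapshot()], [cellData()]
#' @export
setClass("PopulationSnapshot",
  representation(
    time = "numeric", cells = "data.frame",
    nDivisions = "integer", nArrested = "integer"
  )
)

setValidity("PopulationSnapshot", function(object) {
  msg <- character()
  cells <- object@cells
  need <- c("size", "nanog", "nanog2", "arrested")
  if (!all(need %in% names(cells)))
    return(paste("'cells' must have columns", paste(need, collapse = ", ")))
  if (nrow(cells)) {
    if (any(cells$size <= 0)) msg <- c(msg, "all cell sizes must be > 0")
    if (any(cells$nanog < 0)) msg <- c(msg, "all NANOG values must be >= 0")
    if (any(!is.na(cells$nanog2) & cells$nanog2 < 0))
      msg <- c(msg, "all second-reporter values must be >= 0")
  }
  if (object@nArrested != sum(cells$arrested))
    msg <- c(msg, "'nArrested' must equal the number of arrested cells")
  if (length(msg)) msg else TRUE
})

#' Binned probability density over a state variable
#'
#' A normalized histogram-style density over one axis (size or molecules)
#' with a time stamp, used for objective-function evaluation and for the
#' finite-difference/Monte Carlo comparisons.
#'
#' @slot edges ordered bin edges.
#' @slot density per-bin probability density values (integrates to 1).
#' @slot time time stamp (hr).
#'
#' @seealso [densityGrid()], [binDensity()]
#' @export
setClass("DensityGrid",
  representation(edges = "numeric", density = "numeric", time = "numeric")
)

setValidity("DensityGrid", function(object) {
  msg <- character()
  if (length(object@edges) != length(object@density) + 1L)
    return("'edges' must have length(density) + 1 entries")
  if (is.unsorted(object@edges, strictly = TRUE))
    msg <- c(msg, "'edges' must be strictly increasing")
  if (any(object@density < 0)) msg <- c(msg, "'density' must be >= 0 everywhere")
  mass <- sum(object@density * diff(object@edges))
  if (abs(mass - 1) > 1e-6)
    msg <- c(msg, sprintf("density must integrate to 1 (got %.8f)", mass))
  if (length(msg)) msg else TRUE
})

#' Per-cell flow-cytometry-style event table
#'
#' One row per measured cell: a forward-scatter value \code{fsc}
#' (instrument arbitrary units in \[0, 1024\]) and zero or more named
#' fluorescence channels (AU, >= 0). Channel names and acquisition
#' metadata are kept in \code{metadata}.
#'
#' @slot events \code{data.frame} with an \code{fsc} column plus channel
#'   columns.
#' @slot metadata list with at least \code{channels} (character vector of
#'   fluorescence column names); optionally \code{label} and \code{day}.
#'
#' @seealso [eventTable()], [readEventTable()]
#' @export
setClass("EventTable",
  representation(events = "data.frame", metadata = "list")
)

setValidity("EventTable", function(object) {
  msg <- character()
  ev <- object@events
  if (!"fsc" %in% names(ev)) return("'events' must contain an 'fsc' column")
  if (nrow(ev)) {
    if (any(ev$fsc < 0 | ev$fsc > 1024))
      msg <- c(msg, "'fsc' values must lie in [0, 1024]")
    for (ch in object@metadata$channels) {
      if (!ch %in% names(ev)) {
        msg <- c(msg, sprintf("declared channel '%s' missing from events", ch))
      } else if (any(ev[[ch]] < 0)) {
        msg <- c(msg, sprintf("channel '%s' has negative AU values", ch))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' MESF bead calibration curve
#'
#' Log-log linear least-squares fit mapping fluorescence arbitrary units
#' (AU) to molecule counts (MESF units), fitted on bead populations with
#' known molecules per bead.
#'
#' @slot beads \code{data.frame} with columns \code{au} and
#'   \code{molecules}, one row per bead level.
#' @slot slope slope of the least-squares line in log10(AU) vs
#'   log10(molecules) space.
#' @slot intercept intercept of that line.
#'
#' @seealso [fitCalibration()], [auToMolecules()]
#' @export
setClass("CalibrationCurve",
  representation(beads = "data.frame", slope = "numeric", intercept = "numeric")
)

setValidity("CalibrationCurve", function(object) {
  b <- object@beads
  if (!all(c("au", "molecules") %in% names(b)))
    return("'beads' must have columns 'au' and 'molecules'")
  if (nrow(b) < 2L) return("at least 2 bead levels are required")
  if (any(b$au <= 0) || any(b$molecules <= 0))
    return("bead 'au' and 'molecules' must be positive")
  o <- order(b$au)
  if (is.unsorted(b$molecules[o], strictly = TRUE))
    return("'molecules' must increase strictly with 'au'")
  TRUE
})

#' Total/intrinsic/extrinsic squared-noise decomposition
#'
#' Squared-noise triple from a dual-reporter sample, following the
#' Elowitz/Swain estimators: intrinsic noise from the uncorrelated
#' divergence of two identical reporters within cells, extrinsic noise
#' from their covariation across cells.
#'
#' @slot etaTotSq total squared noise (dimensionless).
#' @slot etaIntSq intrinsic squared noise.
#' @slot etaExtSq extrinsic squared noise.
#'
#' @seealso [dualReporterDecomposition()]
#' @export
setClass("NoiseDecomposition",
  representation(etaTotSq = "numeric", etaIntSq = "numeric", etaExtSq = "numeric")
)

setValidity("NoiseDecomposition", function(object) {
  if (abs(object@etaIntSq + object@etaExtSq - object@etaTotSq) > 1e-12 *
        max(1, abs(object@etaTotSq)))
    return("'etaIntSq' + 'etaExtSq' must equal 'etaTotSq'")
  TRUE
})

#' Result of a simulation-based parameter fit
#'
#' @slot params fitted [ModelParams-class].
#' @slot objectiveValue final value of the least-squares density objective.
#' @slot nEvaluations number of objective evaluations consumed.
#' @slot converged logical convergence flag from the optimizer.
#' @slot trace \code{data.frame} of accepted objective values in order.
#'
#' @seealso [fitSizeParams()], [fitNanogParams()]
#' @export
setClass("FitResult",
  representation(
    params = "ModelParams", objectiveValue = "numeric",
    nEvaluations = "integer", converged = "logical", trace = "data.frame"
  )
)

setValidity("FitResult", function(object) {
  if (object@objectiveValue < 0) return("'objectiveValue' must be >= 0")
  TRUE
})

#' Specification for synthetic flow-cytometry data generation
#'
#' @slot params ground-truth [ModelParams-class].
#' @slot nEvents number of cell events to emit.
#' @slot noiseCvMeasurement multiplicative (lognormal) measurement noise
#'   CV applied per channel.
#' @slot beadLevels number of calibration bead populations.
#' @slot seed integer random seed.
#'
#' @seealso [syntheticSpec()], [generatePopulationDataset()]
#' @export
setClass("SyntheticSpec",
  representation(
    params = "ModelParams", nEvents = "integer",
    noiseCvMeasurement = "numeric", beadLevels = "integer", seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nEvents < 1L) msg <- c(msg, "'nEvents' must be >= 1")
  if (object@noiseCvMeasurement < 0) msg <- c(msg, "'noiseCvMeasurement' must be >= 0")
  if (object@beadLevels < 2L) msg <- c(msg, "'beadLevels' must be >= 2")
  if (length(msg)) msg else TRUE
})
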