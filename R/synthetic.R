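## Synthetic flow-cytometry-like datasets with known ground truth: the
## testable stand-in for undeposited hESC flow data. Cell events carry
## multiplicative lognormal measurement noise (flow-standard); the AU
## dynamic range is capped at 1e4 with a saturation flag, mimicking a
## 4-decade cytometer scale.

.AU_SATURATION <- 1e4

.lnorm_sdlog <- function(cv) sqrt(log1p(cv^2))

## multiplicative lognormal noise at the given CV; mean-centered for cell
## channels (mean-preserving measurement noise), median-centered for bead
## ladders (per-level medians recover the nominal values)
.measNoise <- function(n, cv, center = c("mean", "median")) {
  if (cv <= 0) return(rep(1, n))
  s <- .lnorm_sdlog(cv)
  ml <- if (match.arg(center) == "mean") -s^2 / 2 else 0
  rlnorm(n, meanlog = ml, sdlog = s)
}

## The reference calibration: molecules = 100 * AU along the bead ladder
## (slope 1 in log-log space), spanning the 4-decade AU range.
.defaultCalibration <- function() {
  fitCalibration(data.frame(au = c(10, 100, 1000), molecules = c(1e3, 1e4, 1e5)))
}

#' Generate a synthetic cell population dataset with ground truth
#'
#' Runs the \code{FULL} scenario to stationarity at the ground-truth
#' parameters, samples \code{nEvents} cells, maps normalized size to FSC
#' (\code{size * 1024}) and NANOG molecules to fluorescence AU through a
#' generated MESF calibration curve, and applies multiplicative lognormal
#' measurement noise at \code{noiseCvMeasurement} per channel. AU values
#' are capped at 1e4 and flagged in a \code{saturated} column.
#'
#' @param spec a [SyntheticSpec-class].
#' @param k0,kmax,burnInDoublings simulation budget of the pilot
#'   population (defaults reproduce the reference study conditions).
#' @return List with \code{table} (an [EventTable-class] with channels
#'   \code{nanog_au}), \code{groundTruth} (list: parameter values,
#'   calibration curve coefficients, seed, and the noise-free per-cell
#'   sample) and \code{calibration} (the [CalibrationCurve-class] used).
#' @export
generatePopulationDataset <- function(spec, k0 = 5000, kmax = 10000,
                                      burnInDoublings = 2) {
  stopifnot(is(spec, "SyntheticSpec"))
  p <- spec@params
  snap <- stationaryEnsemble(p, k0 = k0, kmax = kmax,
                             burnInDoublings = burnInDoublings,
                             seed = spec@seed)
  cells <- cellData(snap)
  idx <- sample(nrow(cells), spec@nEvents, replace = spec@nEvents > nrow(cells))
  cells <- cells[idx, ]
  calib <- .defaultCalibration()
  fsc <- pmin(cells$size * 1024 * .measNoise(spec@nEvents, spec@noiseCvMeasurement),
              1024)
  au <- moleculesToAu(calib, pmax(cells$nanog, 1)) *
    .measNoise(spec@nEvents, spec@noiseCvMeasurement)
  saturated <- au > .AU_SATURATION
  au <- pmin(au, .AU_SATURATION)
  tab <- eventTable(
    data.frame(fsc = fsc, nanog_au = au, saturated = saturated),
    channels = "nanog_au", label = "synthetic self-renewing population"
  )
  truth <- list(
    params = as.list(paramValues(p)),
    seed = spec@seed,
    noiseCvMeasurement = spec@noiseCvMeasurement,
    calibration = list(slope = calib@slope, intercept = calib@intercept),
    sample = data.frame(size = cells$size, nanog = cells$nanog)
  )
  list(table = tab, groundTruth = truth, calibration = calib)
}

#' Generate a synthetic MESF bead calibration table
#'
#' A geometric ladder of bead populations spanning the AU dynamic range:
#' per-level AU values scatter around the level median with measurement
#' CV ~ 0.19 (the observed dispersion of MESF beads), while the paired
#' molecule counts are exact.
#'
#' @param spec a [SyntheticSpec-class]; \code{beadLevels} sets the number
#'   of levels.
#' @param eventsPerLevel bead events per level.
#' @param beadCv per-level measurement CV (default 0.19).
#' @return List with \code{table} (an [EventTable-class] with columns
#'   \code{au}, \code{molecules}, \code{level}; \code{fsc} is a nominal
#'   constant bead scatter) and \code{levels} (\code{data.frame} of exact
#'   level medians, suitable for [fitCalibration()]).
#' @export
generateBeadTable <- function(spec, eventsPerLevel = 1000L, beadCv = 0.19) {
  stopifnot(is(spec, "SyntheticSpec"))
  set.seed(spec@seed + 1L)
  calib <- .defaultCalibration()
  auMed <- 10^seq(1, 3.5, length.out = spec@beadLevels)
  mol <- auToMolecules(calib, auMed)
  n <- spec@beadLevels * eventsPerLevel
  level <- rep(seq_len(spec@beadLevels), each = eventsPerLevel)
  au <- pmin(auMed[level] * .measNoise(n, beadCv, center = "median"),
             .AU_SATURATION)
  tab <- eventTable(
    data.frame(fsc = rep(256, n), au = au, molecules = mol[level],
               level = level),
    channels = "au", label = "synthetic MESF beads"
  )
  list(table = tab, levels = data.frame(au = auMed, molecules = mol))
}

#' Generate a matched untreated/arrested dataset pair
#'
#' Emulates the data shape of a mitotic-arrest experiment: the untreated
#' table is a stationary \code{FULL}-scenario sample; the arrested table
#' continues the same initial ensemble under \code{BLOCKED_DIVISION} for
#' \code{arrestHours} and is sampled and noised identically.
#'
#' @param spec a [SyntheticSpec-class].
#' @param arrestHours duration of the division block (hr).
#' @param k0,kmax,burnInDoublings pilot-population budget.
#' @return List with \code{untreated} and \code{arrested} (each an
#'   [EventTable-class] with a \code{nanog_au} channel) and
#'   \code{groundTruth} (parameter values, seed, and the noise-free
#'   NANOG samples of both arms).
#' @export
generateArrestPair <- function(spec, arrestHours = 16, k0 = 5000,
                               kmax = 10000, burnInDoublings = 2) {
  stopifnot(is(spec, "SyntheticSpec"))
  p <- spec@params
  base <- stationaryEnsemble(p, k0 = k0, kmax = kmax,
                             burnInDoublings = burnInDoublings,
                             seed = spec@seed)
  cfg <- simulationConfig(k0 = nrow(cellData(base)), kmax = kmax,
                          tTotal = arrestHours, seed = spec@seed + 2L,
                          scenario = "BLOCKED_DIVISION")
  arrested <- runSimulation(p, cfg, init = base)[[1]]
  calib <- .defaultCalibration()
  sampleArm <- function(snap, label) {
    cells <- cellData(snap)
    idx <- sample(nrow(cells), spec@nEvents,
                  replace = spec@nEvents > nrow(cells))
    cells <- cells[idx, ]
    au <- moleculesToAu(calib, pmax(cells$nanog, 1)) *
      .measNoise(spec@nEvents, spec@noiseCvMeasurement)
    fsc <- pmin(cells$size * 1024 *
                  .measNoise(spec@nEvents, spec@noiseCvMeasurement), 1024)
    list(table = eventTable(
           data.frame(fsc = fsc, nanog_au = pmin(au, .AU_SATURATION)),
           channels = "nanog_au", label = label),
         nanog = cells$nanog)
  }
  set.seed(spec@seed + 3L)
  u <- sampleArm(populationSnapshot(cellData(base)), "synthetic untreated")
  a <- sampleArm(arrested, "synthetic mitotic arrest")
  list(
    untreated = u$table, arrested = a$table,
    groundTruth = list(params = as.list(paramValues(p)), seed = spec@seed,
                       arrestHours = arrestHours,
                       untreatedNanog = u$nanog, arrestedNanog = a$nanog)
  )
}

#' Write / read a ground-truth sidecar file
#'
#' Ground-truth records round-trip with their dataset as JSON sidecars,
#' enabling blind parameter-recovery tests.
#'
#' @param truth ground-truth list as produced by the generators.
#' @param path sidecar file path (conventionally
#'   \code{<dataset>.truth.json}).
#' @return [writeGroundTruth()] invisibly returns \code{path};
#'   [readGroundTruth()] returns the ground-truth list.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
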