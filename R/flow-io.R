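## Event-table IO, FSC size transforms and MESF bead calibration.
## The canonical interchange format is tab-delimited text with a header;
## native FCS binary parsing is deliberately out of the core (any reader
## producing a data.frame with an 'fsc' column can feed eventTable()).

#' Read / write per-cell event tables
#'
#' Tab-delimited text with a header row naming the \code{fsc} column and
#' the fluorescence channels. Unknown columns are preserved, and a
#' write/read round trip is value-identical.
#'
#' @param path file path.
#' @param channels optional channel names; defaults to all non-\code{fsc}
#'   numeric columns.
#' @return [readEventTable()] returns an [EventTable-class];
#'   [writeEventTable()] invisibly returns \code{path}.
#' @export
readEventTable <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("format error: empty file: ", path)
  ev <- read.delim(path, check.names = FALSE)
  if (!nrow(ev) && !ncol(ev)) stop("format error: empty file: ", path)
  if (!"fsc" %in% names(ev))
    stop("format error: no 'fsc' column; columns present: ",
         paste(names(ev), collapse = ", "))
  eventTable(ev, channels = channels)
}

#' @rdname readEventTable
#' @param table an [EventTable-class].
#' @export
writeEventTable <- function(table, path) {
  stopifnot(is(table, "EventTable"))
  write.table(eventData(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Normalize forward-scatter values to cell sizes
#'
#' The normalized size is \code{fsc / 1024}, mapping the 10-bit
#' instrument range onto \[0, 1\].
#'
#' @param fsc forward-scatter values (AU in \[0, 1024\]).
#' @return Normalized sizes in \[0, 1\].
#' @examples
#' normalizeFsc(c(0, 512, 1024))  # 0, 0.5, 1
#' @export
normalizeFsc <- function(fsc) {
  if (any(fsc < 0 | fsc > 1024)) stop("'fsc' values must lie in [0, 1024]")
  fsc / 1024
}

#' FSC-to-volume power transform
#'
#' Optional alternative size proxy \code{fsc^(3/2)} (scatter scales
#' roughly with cross-sectional area, volume with the 3/2 power of area);
#' off by default throughout the package.
#'
#' @param fscNorm normalized FSC values, >= 0.
#' @return Transformed values; monotone on \[0, Inf).
#' @examples
#' fscVolumeTransform(4)  # 8
#' @export
fscVolumeTransform <- function(fscNorm) {
  if (any(fscNorm < 0)) stop("'fscNorm' must be >= 0")
  fscNorm^1.5
}

#' Fit an MESF bead calibration curve
#'
#' Least-squares line in log10(AU) vs log10(molecules) space through the
#' bead levels; the conversion in both directions applies the fitted line
#' exactly, so \code{auToMolecules} and \code{moleculesToAu} are exact
#' inverses.
#'
#' @param beads \code{data.frame} with columns \code{au} (fluorescence
#'   AU) and \code{molecules} (MESF molecules per bead), both positive,
#'   \code{molecules} strictly increasing with \code{au}; >= 2 levels.
#' @return A [CalibrationCurve-class].
#' @examples
#' cc <- fitCalibration(data.frame(au = c(10, 1000), molecules = c(1e3, 1e5)))
#' auToMolecules(cc, 100)  # 1e4
#' @export
fitCalibration <- function(beads) {
  beads <- as.data.frame(beads)
  if (!all(c("au", "molecules") %in% names(beads)))
    stop("'beads' must have columns 'au' and 'molecules'")
  if (nrow(beads) < 2L) stop("at least 2 bead levels are required")
  if (any(beads$au <= 0) || any(beads$molecules <= 0))
    stop("bead 'au' and 'molecules' must be positive")
  lx <- log10(beads$au); ly <- log10(beads$molecules)
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  intercept <- mean(ly) - slope * mean(lx)
  new("CalibrationCurve", beads = beads[order(beads$au), , drop = FALSE],
      slope = slope, intercept = intercept)
}

#' @rdname fitCalibration
#' @param curve a [CalibrationCurve-class].
#' @param au fluorescence values (AU, > 0).
#' @export
auToMolecules <- function(curve, au) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (any(au <= 0)) stop("'au' must be positive")
  10^(curve@intercept + curve@slope * log10(au))
}

#' @rdname fitCalibration
#' @param molecules molecule counts (> 0).
#' @export
moleculesToAu <- function(curve, molecules) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (any(molecules <= 0)) stop("'molecules' must be positive")
  10^((log10(molecules) - curve@intercept) / curve@slope)
}

#' Percentile-threshold positivity filter against a control table
#'
#' Marks events as positive when their channel value exceeds the given
#' percentile of an isotype-style control sample, and drops the rest.
#' Synthetic pipelines default to no thresholding; this filter exists for
#' data carrying a measured control.
#'
#' @param table an [EventTable-class].
#' @param control an [EventTable-class] measured with the control
#'   antibody, or a numeric vector of control AU values.
#' @param channel channel name present in both tables.
#' @param percentile control percentile defining positivity (default
#'   0.98).
#' @return The filtered [EventTable-class].
#' @export
isotypeFilter <- function(table, control, channel, percentile = 0.98) {
  stopifnot(is(table, "EventTable"))
  vals <- if (is(control, "EventTable")) eventData(control)[[channel]] else control
  if (is.null(vals)) stop("control lacks channel '", channel, "'")
  thr <- quantile(vals, percentile, names = FALSE)
  ev <- eventData(table)
  if (is.null(ev[[channel]])) stop("table lacks channel '", channel, "'")
  eventTable(ev[ev[[channel]] > thr, , drop = FALSE],
             channels = channelNames(table),
             label = table@metadata$label, day = table@metadata$day)
}
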