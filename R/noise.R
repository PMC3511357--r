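## Population statistics: CV, total noise, correlation, LN/HN gating and
## the dual-reporter intrinsic/extrinsic decomposition.
##
## Moment convention: population moments (divide by n), because PBE
## densities are full-ensemble objects; at the sample sizes used here
## (>= 1e4 cells) the distinction from the n-1 convention is immaterial.

.popVar <- function(x) mean((x - mean(x))^2)

#' Coefficient of variation
#'
#' Sample standard deviation over sample mean, under the population-moment
#' (divide-by-n) convention.
#'
#' @param values numeric sample (n >= 2, positive mean).
#' @return Dimensionless CV; invariant under positive rescaling.
#' @examples
#' coefficientOfVariation(c(1, 3))  # 0.5
#' @export
coefficientOfVariation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m <= 0) stop("mean must be positive")
  sqrt(.popVar(values)) / m
}

#' Total noise of a distribution
#'
#' Variance over squared mean, the squared coefficient of variation; the
#' standard definition of total noise for a protein distribution.
#'
#' @param values numeric sample (n >= 2, positive mean).
#' @return Dimensionless total noise (equals \code{coefficientOfVariation(values)^2}).
#' @examples
#' totalNoise(c(1, 3))  # 0.25
#' @export
totalNoise <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m <= 0) stop("mean must be positive")
  .popVar(values) / m^2
}

#' Pearson correlation between cell size and NANOG content
#'
#' @param table a two-column \code{data.frame} (or matrix) of paired
#'   size/NANOG values, or a [PopulationSnapshot-class].
#' @return Pearson product-moment correlation coefficient in \[-1, 1\].
#' @examples
#' sizeNanogCorrelation(data.frame(x = c(1, 2, 3), N = c(2, 1, 3)))  # 0.5
#' @export
sizeNanogCorrelation <- function(table) {
  if (is(table, "PopulationSnapshot")) table <- cellData(table)[c("size", "nanog")]
  table <- as.data.frame(table)
  stopifnot(ncol(table) >= 2L)
  x <- table[[1]]; y <- table[[2]]
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (.popVar(x) == 0 || .popVar(y) == 0)
    stop("zero variance in one of the margins")
  cor(x, y)
}

#' LN/HN gate fractions
#'
#' Defines the NANOG-low (LN) and NANOG-high (HN) regions as the 20th and
#' 80th percentiles of a reference population and reports the fractions
#' of a target population falling below and above them. Comparisons are
#' strict; values tied with a threshold are broadcast to the lower region
#' (deterministic tie-breaking: ties at the LN threshold count as LN,
#' ties at the HN threshold do not count as HN).
#'
#' @param reference numeric reference sample defining the gates (for the
#'   self-gated reference, both fractions are 0.20 by construction).
#' @param target numeric sample to which the gates are applied.
#' @param probs percentiles defining the LN and HN thresholds.
#' @param lowerDetectionLimit optional detection threshold; values at or
#'   below it are dropped from both samples before gating (mimics
#'   isotype-based positivity gating; default none).
#' @return Named numeric vector with \code{lnFraction} and
#'   \code{hnFraction}.
#' @examples
#' set.seed(1)
#' ref <- rlnorm(1e4)
#' gateLnHn(ref, ref * 100)  # c(0, 1)
#' @export
gateLnHn <- function(reference, target, probs = c(0.2, 0.8),
                     lowerDetectionLimit = NULL) {
  if (!length(reference) || !length(target)) stop("empty sample")
  if (!is.null(lowerDetectionLimit)) {
    reference <- reference[reference > lowerDetectionLimit]
    target <- target[target > lowerDetectionLimit]
    if (!length(reference) || !length(target))
      stop("no events above the detection limit")
  }
  thr <- quantile(reference, probs, names = FALSE, type = 7)
  c(lnFraction = mean(target <= thr[1]), hnFraction = mean(target > thr[2]))
}

#' Intrinsic/extrinsic noise decomposition from a dual-reporter sample
#'
#' Elowitz/Swain estimators on paired reporter levels \eqn{(N_c, N_y)}:
#' \deqn{\eta_{int}^2 = E[(N_c - N_y)^2] / (2 E[N_c] E[N_y])}
#' \deqn{\eta_{ext}^2 = (E[N_c N_y] - E[N_c] E[N_y]) / (E[N_c] E[N_y])}
#' \deqn{\eta_{tot}^2 = \eta_{int}^2 + \eta_{ext}^2}
#' Intrinsic noise measures the uncorrelated divergence of two
#' identically regulated reporters within single cells (here: independent
#' expression-noise realizations and independent partition draws);
#' extrinsic noise measures correlated cell-to-cell differences (here:
#' division and dilution history shared by both reporters). The
#' additivity \eqn{\eta_{int}^2 + \eta_{ext}^2 = \eta_{tot}^2} holds
#' exactly by construction.
#'
#' @param pairs two-column \code{data.frame} (or matrix) of paired
#'   reporter levels, or a [PopulationSnapshot-class] from a dual-reporter
#'   run (columns \code{nanog}, \code{nanog2}).
#' @return A [NoiseDecomposition-class].
#' @examples
#' dualReporterDecomposition(data.frame(Nc = c(10, 12), Ny = c(12, 10)))
#' @export
dualReporterDecomposition <- function(pairs) {
  if (is(pairs, "PopulationSnapshot"))
    pairs <- cellData(pairs)[c("nanog", "nanog2")]
  pairs <- as.data.frame(pairs)
  nc <- pairs[[1]]; ny <- pairs[[2]]
  if (length(nc) < 10L) stop("need at least 10 reporter pairs")
  if (any(is.na(nc)) || any(is.na(ny))) stop("missing reporter values")
  mc <- mean(nc); my <- mean(ny)
  if (mc <= 0 || my <= 0) stop("nonpositive channel mean")
  etaInt <- mean((nc - ny)^2) / (2 * mc * my)
  etaExt <- (mean(nc * ny) - mc * my) / (mc * my)
  new("NoiseDecomposition", etaTotSq = etaInt + etaExt,
      etaIntSq = etaInt, etaExtSq = etaExt)
}
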