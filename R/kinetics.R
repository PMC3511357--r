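## Single-cell kinetic laws: growth, division hazard, partitioning, NANOG SDE.

## Hazard cap applied where the Gaussian survivor function underflows; keeps
## quiescence-interval root finding finite.
.HAZARD_CAP <- 1e4

#' Single-cell exponential growth rate
#'
#' Size grows exponentially, \eqn{r_1(x) = (\ln 2 / T_d)\, x}, the unique
#' rate law giving exact size doubling over one doubling time.
#'
#' @param x normalized cell size(s), > 0 (0 is allowed and maps to rate 0).
#' @param params a [ModelParams-class].
#' @return Growth rate(s), size units per hour.
#' @examples
#' p <- hescParams()
#' growthRate(0.5, p)
#' @export
growthRate <- function(x, params) {
  stopifnot(is(params, "ModelParams"))
  if (any(x < 0)) stop("'x' must be >= 0")
  (log(2) / params@doublingTime) * x
}

#' Size-gated division hazard
#'
#' The per-cell division rate \eqn{\Gamma(x) = r_1(x) g(x) / (1 -
#' \int_0^x g(s) ds)}, where \eqn{g} is the Gaussian density of mitotic
#' sizes with mean \code{mu} and st.dev. \code{sigma}. The hazard vanishes
#' in the far-left tail and diverges as the Gaussian CDF approaches 1; it
#' is capped at \code{1e4}/hr where the survivor function underflows, so
#' the returned value is always finite and never \code{NaN}.
#'
#' @param x normalized cell size(s), > 0.
#' @param params a [ModelParams-class].
#' @return Division hazard(s), 1/hr.
#' @examples
#' p <- hescParams()
#' divisionRate(p@mu, p)  # 2 * r1(mu) * g(mu)
#' @export
divisionRate <- function(x, params) {
  stopifnot(is(params, "ModelParams"))
  if (any(x <= 0)) stop("'x' must be > 0")
  surv <- pnorm(x, params@mu, params@sigma, lower.tail = FALSE)
  g <- dnorm(x, params@mu, params@sigma)
  rate <- growthRate(x, params) * g / surv
  rate[!is.finite(rate) | rate > .HAZARD_CAP] <- .HAZARD_CAP
  ## survivor underflow with negligible density: far right tail, treat as cap
  rate[surv == 0] <- .HAZARD_CAP
  rate
}

#' Sample symmetric beta partition fractions
#'
#' Draws daughter fractions \eqn{f \sim Beta(q, q)}; a mother of size
#' \eqn{x'} splits into daughters \eqn{f x'} and \eqn{(1-f) x'}. The same
#' law (same \code{q}) is used for NANOG partitioning.
#'
#' @param n number of draws.
#' @param q beta shape parameter (> 0); alternatively a
#'   [ModelParams-class] whose \code{q} slot is used.
#' @return Numeric vector of fractions in (0, 1).
#' @examples
#' set.seed(1)
#' mean(samplePartitionFraction(1e4, 39.519))  # ~0.5
#' @export
samplePartitionFraction <- function(n, q) {
  if (is(q, "ModelParams")) q <- q@q
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0)
    stop("'q' must be a single positive number")
  rbeta(n, q, q)
}

#' One Euler-Maruyama step of the NANOG birth-death SDE
#'
#' Advances \eqn{N} by \eqn{N + (\alpha - d N)\,dt + \delta \sqrt{dt}\, Z}
#' with \eqn{Z \sim Normal(0,1)}, clipped below at 0 (copy numbers are
#' nonnegative; at the reference parameter scales clipping is rare).
#' Vectorized over \code{N}.
#'
#' @param N NANOG copy number(s), >= 0.
#' @param dt time step (hr), > 0.
#' @param params a [ModelParams-class].
#' @return Updated copy number(s).
#' @examples
#' p <- hescParams()
#' nanogStep(p@alpha / p@d, 0.01, modelParams(p@mu, p@sigma, p@q,
#'           p@alpha, p@d, 0, p@doublingTime))  # deterministic fixed point
#' @export
nanogStep <- function(N, dt, params) {
  stopifnot(is(params, "ModelParams"))
  if (any(N < 0)) stop("'N' must be >= 0")
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    stop("'dt' must be a single positive number")
  drift <- (params@alpha - params@d * N) * dt
  noise <- if (params@delta > 0) params@delta * sqrt(dt) * rnorm(length(N)) else 0
  pmax(N + drift + noise, 0)
}
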