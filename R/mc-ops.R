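## Reference R implementations of the Monte Carlo event-loop operations.
## runSimulation() executes the same algorithm in compiled code; these
## functions expose the individual steps for analysis and testing.

#' Summed division hazard of an ensemble
#'
#' \eqn{\Lambda = \sum_i \Gamma(x_i)} over non-arrested cells: the rate of
#' the next division event anywhere in the population.
#'
#' @param snapshot a [PopulationSnapshot-class].
#' @param params a [ModelParams-class].
#' @return Total hazard (1/hr).
#' @export
totalHazard <- function(snapshot, params) {
  cells <- cellData(snapshot)
  live <- !cells$arrested
  if (nrow(cells) == 0L || !any(live))
    stop("no division possible: population empty or fully arrested")
  sum(divisionRate(cells$size[live], params))
}

#' Sample the interval of quiescence
#'
#' Solves \eqn{1 - \exp(-\int_t^{t+T} \Lambda(s) ds) = u} for the waiting
#' time \eqn{T} until the next division anywhere in the population, with
#' cell sizes growing along their explicit-Euler trajectories during the
#' lookahead (left-rectangle quadrature on steps of at most \code{dt}).
#' Newton-Raphson from the frozen-hazard solution
#' \eqn{T_0 = -\ln(1-u)/\Lambda}, tolerance \code{1e-6} hr, at most 50
#' iterations, with a bisection fallback; never returns \code{NaN}.
#'
#' @param snapshot a [PopulationSnapshot-class].
#' @param params a [ModelParams-class].
#' @param u uniform(0,1) variate driving the inversion.
#' @param dt quadrature/growth step (hr).
#' @param horizon upper bound on the lookahead (hr); \code{Inf} by
#'   default. Returns \code{Inf} when no division occurs within it.
#' @return Interval \eqn{T > 0} (hr), monotone increasing in \code{u}.
#' @export
sampleQuiescenceInterval <- function(snapshot, params, u, dt = 0.01,
                                     horizon = Inf) {
  stopifnot(length(u) == 1L, u > 0, u < 1)
  cells <- cellData(snapshot)
  sizes <- cells$size[!cells$arrested]
  if (!length(sizes)) stop("no division possible: population fully arrested")
  target <- -log1p(-u)
  kg <- if (is.finite(params@doublingTime)) log(2) / params@doublingTime else 0

  phi <- function(T) { # returns c(integral, end hazard)
    acc <- 0; rem <- T; s <- sizes
    lam <- sum(divisionRate(s, params))
    while (rem > 1e-12) {
      h <- min(dt, rem)
      acc <- acc + lam * h
      s <- s + kg * s * h
      rem <- rem - h
      lam <- sum(divisionRate(s, params))
    }
    c(acc, lam)
  }

  lam0 <- sum(divisionRate(sizes, params))
  if (lam0 > 0 && target <= lam0 * dt) { # single-rectangle regime, exact
    T <- target / lam0
    if (T <= horizon) return(T)
  }
  if (is.finite(horizon) && phi(horizon)[1] < target) return(Inf)
  hi <- if (is.finite(horizon)) horizon else {
    g <- max(if (lam0 > 0) 2 * target / lam0 else params@doublingTime, dt)
    while (phi(g)[1] < target) g <- 2 * g
    g
  }
  lo <- 0
  T <- min(if (lam0 > 0) target / lam0 else hi, hi)
  for (it in seq_len(50L)) {
    p <- phi(T)
    f <- p[1] - target
    if (f > 0) hi <- T else lo <- T
    step <- if (p[2] > 0) f / p[2] else 0
    Tn <- T - step
    if (abs(Tn - T) < 1e-6) return(max(Tn, 1e-12))
    if (!(Tn > lo && Tn < hi) || p[2] <= 0) Tn <- 0.5 * (lo + hi)
    T <- Tn
  }
  while (hi - lo > 1e-9) { # bisection fallback
    mid <- 0.5 * (lo + hi)
    if (phi(mid)[1] > target) hi <- mid else lo <- mid
  }
  0.5 * (lo + hi)
}

#' Select the dividing cell
#'
#' Identifies the cell \eqn{j} undergoing division with probability
#' \eqn{\Gamma(x_j)/\Lambda} by cumulative-sum inversion of a uniform
#' variate.
#'
#' @param snapshot a [PopulationSnapshot-class].
#' @param params a [ModelParams-class].
#' @param u uniform(0,1) variate.
#' @return Index of the dividing cell.
#' @export
selectDividingCell <- function(snapshot, params, u) {
  stopifnot(length(u) == 1L, u >= 0, u <= 1)
  cells <- cellData(snapshot)
  haz <- ifelse(cells$arrested, 0, divisionRate(pmax(cells$size, 1e-300), params))
  lam <- sum(haz)
  if (lam <= 0) stop("no division possible: zero total hazard")
  j <- findInterval(u * lam, cumsum(haz), left.open = TRUE) + 1L
  min(j, nrow(cells))
}

#' Advance every cell over a quiescence interval
#'
#' Integrates size by explicit Euler on the exponential growth law
#' (arrested cells keep their size fixed) and NANOG (plus the second
#' reporter, when present) by Euler-Maruyama sub-steps of at most
#' \code{dt} for all cells, including arrested ones.
#'
#' @param snapshot a [PopulationSnapshot-class].
#' @param interval elapsed time (hr), >= 0.
#' @param params a [ModelParams-class].
#' @param dt maximum sub-step (hr).
#' @return The advanced [PopulationSnapshot-class].
#' @export
advancePopulation <- function(snapshot, interval, params, dt = 0.01) {
  stopifnot(interval >= 0)
  cells <- cellData(snapshot)
  kg <- if (is.finite(params@doublingTime)) log(2) / params@doublingTime else 0
  dual <- !all(is.na(cells$nanog2))
  rem <- interval
  while (rem > 1e-12) {
    h <- min(dt, rem)
    grow <- !cells$arrested
    cells$size[grow] <- cells$size[grow] * (1 + kg * h)
    cells$nanog <- nanogStep(cells$nanog, h, params)
    if (dual) cells$nanog2 <- nanogStep(cells$nanog2, h, params)
    rem <- rem - h
  }
  populationSnapshot(cells, time = snapshotTime(snapshot) + interval,
                     nDivisions = snapshot@nDivisions,
                     nArrested = snapshot@nArrested)
}

#' Divide one cell into two daughters
#'
#' Replaces cell \code{j} by two daughters: size split by one Beta(q, q)
#' draw and NANOG by an independent draw (each reporter by its own draw
#' when a second reporter is present). Below \code{kmax} both daughters
#' join the ensemble (constant-volume phase); at \code{kmax} the second
#' daughter replaces a uniformly chosen other cell (constant-number
#' phase). Size and NANOG sums are conserved exactly.
#'
#' @param snapshot a [PopulationSnapshot-class].
#' @param j index of the dividing cell (must not be arrested).
#' @param params a [ModelParams-class].
#' @param kmax ensemble cap; \code{Inf} keeps the constant-volume phase.
#' @return The post-division [PopulationSnapshot-class].
#' @export
divideCell <- function(snapshot, j, params, kmax = Inf) {
  cells <- cellData(snapshot)
  n <- nrow(cells)
  if (!(j >= 1 && j <= n)) stop("cell index out of range")
  if (cells$arrested[j]) stop("cannot divide an arrested cell")
  clampF <- function(f) min(max(f, 1e-12), 1 - 1e-12)
  f3 <- clampF(samplePartitionFraction(1L, params))
  f4 <- clampF(samplePartitionFraction(1L, params))
  dual <- !is.na(cells$nanog2[j])
  f5 <- if (dual) clampF(samplePartitionFraction(1L, params)) else NA_real_
  mother <- cells[j, ]
  d1 <- mother; d2 <- mother
  d1$size <- f3 * mother$size;        d2$size <- (1 - f3) * mother$size
  d1$nanog <- f4 * mother$nanog;      d2$nanog <- (1 - f4) * mother$nanog
  if (dual) {
    d1$nanog2 <- f5 * mother$nanog2;  d2$nanog2 <- (1 - f5) * mother$nanog2
  }
  cells[j, ] <- d1
  if (n < kmax) {
    cells <- rbind(cells, d2)
  } else {
    r <- sample(setdiff(seq_len(n), j), 1L)
    cells[r, ] <- d2
  }
  populationSnapshot(cells, time = snapshotTime(snapshot),
                     nDivisions = snapshot@nDivisions + 1L)
}
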