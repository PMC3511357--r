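## Shared fixtures for the test suite, built in code.

## Reference kinetic parameters with the closed-form doubling time.
refParams <- function() hescParams()

## A light parameter set for fast Monte Carlo property tests: same size
## law, reduced NANOG scales keep nothing special -- the dynamics are the
## reference ones, only ensemble sizes shrink in the configs below.
smallConfig <- function(..., seed = 1L) {
  defaults <- list(k0 = 200L, kmax = 400L, tTotal = 10, dt = 0.01,
                   seed = seed, scenario = "FULL")
  do.call(simulationConfig, modifyList(defaults, list(...)))
}

## Parameters with division switched off within the simulated horizon:
## the mitotic-size law sits far above any size reachable during the run.
noDivisionParams <- function(delta = 0) {
  modelParams(mu = 0.95, sigma = 0.01, q = 39.519,
              alpha = 7.87e3, d = 7.61e-2, delta = delta,
              doublingTime = 9.838164)
}

## Ensemble with known sizes for hazard/selection tests.
snapshotOfSizes <- function(sizes, nanog = 5e4) {
  populationSnapshot(data.frame(size = sizes, nanog = nanog))
}
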