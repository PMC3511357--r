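# stempbe

Stochastic population balance modeling of cell size and NANOG
heterogeneity in self-renewing human embryonic stem cell (hESC)
populations.

Cultured hESCs keep broad but time-invariant distributions of size and
of the pluripotency factor NANOG. `stempbe` is for quantitative stem
cell biologists and modelers who want to ask *where that heterogeneity
comes from*: how much is stochastic gene expression, and how much is
the random partitioning of cellular content when a cell divides?

## The model

Each cell carries a normalized size *x* and a NANOG copy number *N*:

- size grows exponentially, *r*₁(*x*) = (ln 2 / *T*_d) · *x*;
- division fires with the size-gated hazard
  Γ(*x*) = *r*₁(*x*) *g*(*x*) / (1 − ∫₀ˣ *g*(*s*) d*s*), where *g* is
  the Gaussian density of mitotic sizes (mean μ, st.dev. σ);
- at division, size and NANOG are split between the daughters by
  independent symmetric Beta(*q*, *q*) fractions (content conserved
  exactly);
- between divisions NANOG follows the stochastic differential equation
  d*N* = (α − *d N*) d*t* + δ d*W* (Euler–Maruyama, reflected at zero
  copies).

The population is solved by a constant-volume/constant-number Monte
Carlo algorithm based on interval-of-quiescence sampling
(`runSimulation()`), with an independent finite-difference solution of
the size-structured population balance equation as a cross-check
(`stationarySizeDistribution()`). Scenario switches reproduce the
biological comparisons: full model, division-only
(`NO_EXPRESSION_NOISE`), mitotic arrest (`BLOCKED_DIVISION`), and a
virtual two-reporter experiment (`DUAL_REPORTER`) whose
intrinsic/extrinsic decomposition quantifies the partitioning share of
the total NANOG noise. Parameter estimation (`fitSizeParams()`,
`fitNanogParams()`), MESF bead calibration (`fitCalibration()`), and a
synthetic flow-cytometry data generator with ground-truth sidecars
round out the pipeline. See the methods vignette
(`vignettes/stempbe-methods.Rmd`) for the full account.

## A worked example

```r
library(stempbe)

params <- hescParams()   # reference hESC kinetics
params
#> ModelParams
#>   mitotic size: mu = 0.463, sigma = 0.1; partition q = 39.52
#>   NANOG: alpha = 7870 molecules/hr, d = 0.0761 /hr, delta = 1.74e+04 molecules/hr
#>   doubling time: 9.838 hr

cfg <- simulationConfig(k0 = 1000, kmax = 2000,
                        tTotal = 4 * params@doublingTime, seed = 1)
snap <- runSimulation(params, cfg)[[1]]
snap
#> PopulationSnapshot at t = 39.35 hr: 2000 cells (0 arrested), 5146 divisions
#>   mean size 0.3079, mean NANOG 5.712e+04 molecules

str(snapshotSummary(snap))
#> List of 9
#>  $ time         : num 39.4
#>  $ n            : int 2000
#>  $ meanSize     : num 0.308
#>  $ meanNanog    : num 57120
#>  $ cvNanog      : num 0.594
#>  $ totalNoise   : num 0.353
#>  $ corrSizeNanog: num 0.313
#>  $ nDivisions   : int 5146
#>  $ nArrested    : int 0
```

After four doubling times the 2000-cell ensemble is stationary: the
mean NANOG level (5.7 × 10⁴ molecules/cell) sits at the
production–degradation–dilution balance, the coefficient of variation
(0.59) reflects both noise sources acting together, and the positive
size–NANOG correlation (0.31) arises because both quantities build up
together along the cell cycle. Re-running a scenario with
`NO_EXPRESSION_NOISE` (partitioning as the only stochastic source)
shrinks the CV to ≈ 0.25 — the comparison at the heart of the
analysis.

A YAML-driven command line (`inst/scripts/stempbe-cli.R`) wraps the
same functionality: `simulate`, `fit` and `synth` subcommands write
snapshot tables, summaries, fit results and synthetic datasets as
delimited text with resolved-config sidecars.

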