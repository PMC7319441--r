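# cladoclim

Linking trait disparification and diversification of a clade to
paleoclimate change, on time-calibrated phylogenies.

`cladoclim` is an R package for the comparative workflow used to ask
whether a clade radiated adaptively and whether its tempo tracked
climate: it couples **disparity-through-time** statistics for a
continuous trait (body size) with a **net diversification
rate-through-time** series derived from posterior rate-shift
configurations, and regresses both against paleoclimate series with
**generalized least squares under continuous-time autocorrelation**.
Every stage is also backed by a seeded synthetic-data generator, so the
whole pipeline can be exercised end-to-end with known ground truth.

## The statistics

Given an ultrametric chronogram (ages in Ma) and per-taxon trait values
`x` (here mean `ln(10 × body length in mm)` per genus):

* **Disparity** of a tip set is the mean squared pairwise difference
  `D(x) = 2/(n(n−1)) Σ_{i<j} (x_i − x_j)²`.
* The **DTT curve** evaluates, just below each internal-node age, the
  mean over all live lineages of (subtended-clade disparity) /
  (whole-tree disparity); it starts at 1 at the root and decays towards
  0. A null envelope comes from Brownian-motion (BM) simulation on the
  same tree (default 10,000 replicates).
* **MDI** is the signed area between the observed curve and the null
  reference over relative time; negative MDI means disparity is
  partitioned *among* rather than *within* subclades — the adaptive
  radiation signature. The **disparity deviation** `DD_i = obs_i −
  null_i` resolves this per node age.
* **Pagel's λ** is estimated by maximum likelihood under
  `x ~ N(z0·1, σ²C(λ) + diag(se²))`, where `C(λ)` has its off-diagonal
  shared-path entries scaled by λ and `se` is the per-taxon measurement
  error; λ = 1 is Brownian motion, λ = 0 no phylogenetic signal.
* **Rate through time (DRTT)**: each branch alive at age `t` carries
  `r = λ0·exp(z·(t0 − t)) − μ0` per rate process of an event
  configuration; per-lineage rates are averaged over configurations and
  the series is the **median across lineages**.
* **Climate regression**: ΔT (°C), logit(pO₂/100) and ln(cCO₂) are
  spline-harmonised onto the node-age grid and all 7 predictor subsets
  are fit by ML GLS with CAR(1) errors `cov(e_i,e_j) = σ²e^{−φ|t_i−t_j|}`,
  ranked by AIC with Akaike weights, likelihood-ratio pseudo-R² and
  standardized coefficients; rate and DD are then correlated per
  geological stage (root–145, 145–66, 66–0 Ma).

## Worked example

```r
library(cladoclim)

tree   <- simulate_bd_tree(lambda = 0.1, mu = 0.02, n = 50, seed = 101)
traits <- simulate_bm_traits(tree, sigma2 = 0.05, z0 = 3,
                             lambda_signal = 1, se = 0.05, seed = 102)

fit_lambda(tree, traits)
#> Pagel's lambda fit (ML)
#>   lambda  = 1.0000
#>   sigma^2 = 0.0531658 per Myr
#>   z0      = 3.7080
#>   logLik  = -46.6939  (n = 50 tips, measurement error included)

res <- dtt(tree, traits, nsim = 1000, seed = 103)
res
#> Disparity through time
#>   grid: 49 node ages, root 38.67 Ma
#>   null: 1000 BM simulations (reference: median)
#>   MDI = -0.0384
```

The traits were generated under Brownian motion with λ = 1, and the fit
recovers λ = 1.0000; the MDI of −0.038 is the small deviation expected
when the observed curve is itself one Brownian draw against a
1000-replicate null. Rates from a single exponentially accelerating
process evaluate on the same node-age grid:

```r
cfg  <- simulate_event_configuration(tree, root_process = c(0.1, 0.003, 0.02))
rate <- rate_through_time(tree, cfg, grid = res$dd$age)
head(rate, 3)
#>        age       rate
#> 1 38.67383 0.08000000
#> 2 37.44869 0.08036822
#> 3 31.22288 0.08226045
```

At the root (38.67 Ma) the net rate is `λ0 − μ0 = 0.08`; it then grows
as `0.1·e^{0.003·(t0−t)} − 0.02` towards the present. `run_pipeline()`
chains all stages — λ fit, DTT/MDI/DD, DRTT, climate harmonisation,
per-stage AIC model selection and staged correlations — from one config
and master seed, writing tables, figures, a JSON summary and a
reproducibility manifest.

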