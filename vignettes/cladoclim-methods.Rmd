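---
title: "Methods: disparity, diversification and paleoclimate on chronograms"
author: "cladoclim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disparity, diversification and paleoclimate on chronograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladoclim)
```

`cladoclim` implements the comparative workflow that asks, for a clade with
an ultrametric, time-calibrated phylogeny, (i) whether a continuous trait
(body size) diversified *among* or *within* subclades relative to a
Brownian-motion expectation, (ii) how the clade's net diversification rate
moved through time, and (iii) whether either series tracks paleoclimate.
This vignette records the models, conventions, numerical choices and known
limitations; the empirical behaviour it cites is exactly what the package's
test suite computes.

## Chronograms and time conventions

All ages are in Ma before present, increasing towards the root; tips sit at
age 0 and the crown node at the root age. `as_chronogram()` enforces
rootedness, non-negative branch lengths, unique tip labels and
ultrametricity within an absolute tolerance (default `1e-6 ×` root age —
real dated trees carry rounding error); tips inside tolerance are snapped
to exactly age 0 by adjusting pendant branches. A branch subtending node
`k` occupies the half-open interval `[age(k), age(parent(k)))`, so every
age maps each extant lineage to exactly one branch; queries at exactly the
root age return the crown lineages. Polytomies are resolved by uniform
random sequential binarisation with zero-length branches
(`resolve_polytomies()`, seeded); node ages and total branch length are
unchanged, and all downstream statistics are invariant to which resolution
is drawn.

## Disparity through time

The disparity of a tip set is the mean squared pairwise difference,
`2/(n(n−1)) Σ_{i<j}(x_i − x_j)²` (sets of fewer than two values have
disparity 0). The common description "mean of the elements of the distance
matrix" is ambiguous between squared and absolute differences; squared is
the field's default and ours, with `metric = "absolute"` available.

The DTT grid is the set of internal-node ages in descending order. At the
root the curve is 1 by definition (the whole clade against itself). At any
younger node age `t` the curve is evaluated *just below* `t`: a node
splitting exactly at `t` contributes its daughter lineages separately, each
contributing the disparity of its subtended tips divided by the whole-tree
disparity, and single-tip lineages contribute 0 — which is what drives the
curve towards 0 at the present. Simulated trees can carry an internal node
at exactly age 0 (a birth–death simulation stopped at the instant the
target tip count is reached); "just below 0" is then taken as the limit
from above, so the degenerate cherry counts as one two-tip lineage.

The null envelope (`dtt_null()`) simulates Brownian traits on the same
tree — the relative curve is invariant to the Brownian rate, so no rate
parameter is exposed — and summarises the simulated curves pointwise by
median, mean and 2.5%/97.5% quantiles (a pointwise, not simultaneous,
band). The reference curve for MDI and the disparity deviations is the
pointwise **median** by default, matching the single "simulated curve" that
these statistics are defined against; the mean is available via
`reference = "mean"`. Under a Brownian truth the deviation of the observed
curve's *mean* from the null *median* is a small skewness effect; with the
mean reference the expectation is exactly zero. The calibration test
(100-tip tree, 200 Brownian replicates against a 1000-draw envelope)
checks both that the grid-averaged disparity deviation is within
Monte-Carlo error of zero and that ~95% of pointwise deviations fall
inside the 95% band.

MDI integrates `observed − reference` against relative time (0 at the
root, 1 at the present) by a left step rule, with the terminal segment
extended to relative time 1 at the curves' last values. This matches the
stepwise semantics of the node-age grid and invents no interpolation; MDI
is exactly 0 for the reference against itself and linear in a constant
vertical offset.

## Phylogenetic signal with measurement error

`fit_lambda()` maximises the likelihood of
`x ~ N(z0·1, σ²C(λ) + diag(se²))`, where `C` is the shared-path-length
matrix and `C(λ)` scales its off-diagonal entries by λ ∈ [0, 1]. Per-taxon
squared standard errors enter as known measurement variance (the protocol
summarises each genus by the mean, SD and SE of `ln(10 × length in mm)`
over its species; the `10×` factor only shifts the mean but is kept so
reported values stay on the conventional scale). `use_se = FALSE` disables
the error term for sensitivity checks. `z0` is profiled analytically by
the GLS mean; `(λ, σ²)` are optimised by bounded quasi-Newton from five
starting values of λ spread over [0, 1], which avoids trapping at the
bounds. On a star phylogeny the likelihood is constant in λ and the fit
reports the degeneracy (`lambda = NA`) rather than an arbitrary interior
optimum. The Brownian trait generator applies λ by rescaling internal
branch contributions (equivalently, the off-diagonal covariance), the same
definition the fitter uses, so recovery tests are self-consistent — and
the draw is made by branch increments on the rescaled tree, which remains
exact when the covariance matrix itself is singular (zero-length cherries).

## Rate through time from event configurations

The reversible-jump sampler that produces posterior rate-shift
configurations is out of scope; the package consumes its output (or
simulates it). An event configuration assigns every branch to one process
with speciation `λ(t) = λ0·e^{z(t0 − t)}` (elapsed time from the process
start `t0`), constant extinction `μ0`, and `r = λ − μ`. A shift at node
`k` governs the branches of `k`'s subtree unless overridden by a nested,
more recent shift; the background process starts at the root. The DRTT
series follows the stated aggregation order — per-lineage mean over
configurations first, then the median across the lineages alive at each
grid age (midpoint rule for even counts), over *all* lineages of the tree
alive at `t` (whether the posterior's own summary restricted to lineages
with sampled descendants is unknowable from the description; all-lineages
is the reproducible choice). Clade sampling fractions are bookkeeping:
`tips/richness` per named clade with a global probability defaulting to
1.0; pooled or split richness conventions are expressed as input rows, not
code.

## Climate harmonisation and GLS

CO₂ is log-transformed and O₂ logit-transformed on the proportion scale
(`pO₂/100` — the only reading bounded in (0, 1)); temperature deviation
passes through. Natural cubic splines interpolate each (transformed)
variable onto the regression grid, refusing extrapolation beyond the
source span. The regression grid is the disparity-deviation node-age grid,
restricted to the climate span; the rate series is interpolated linearly
onto it.

`fit_gls_car1()` fits `y = Xb + e` with
`cov(e_i, e_j) = σ²·exp(−φ|t_i − t_j|)` — the continuous-time AR(1), the
standard structure for irregular age grids — by ML, not REML, because AIC
comparisons span different fixed-effects structures. For fixed φ the GLS
coefficients and σ² are profiled analytically; φ is optimised on
`[0, 50/span]` by a coarse log-spaced grid followed by local refinement
(the profile likelihood in φ need not be unimodal). Note the limits:
φ → ∞ is independence (OLS); φ = 0 is the *perfectly correlated* limit.
AIC counts `k = ncol(X) + 2` free parameters (coefficients, φ, σ²).
Coefficient p-values use t statistics on `n − ncol(X)` df and are
approximate under estimated φ. Per-stage fits re-estimate φ rather than
sharing one value across stages: stages are long enough to inform φ and
nothing forces a common error structure.

`select_models()` fits all 7 non-empty subsets of {ΔT, logit pO₂,
ln cCO₂} plus the intercept-only null, ranks by AIC, computes Akaike
weights over the successful fits, flags `dAIC < 2` models co-best, and
attaches standardized coefficients `β_j = b_j·sd(x_j)/sd(y)` to co-best
multiple regressions. The pseudo-R² is the likelihood-ratio form
`1 − exp(−(2/n)(ℓ − ℓ0))`, by default rescaled by its Nagelkerke maximum
`1 − exp((2/n)ℓ0)`. That maximum is a true bound only for non-positive
log-likelihoods; continuous responses can have positive log-likelihoods,
in which case the rescaling is skipped and the raw form returned, keeping
the statistic in [0, 1).

Staged Pearson correlations split the grid at 145 and 66 Ma with
closed-left intervals (`age ≥ 145` early; `66 ≤ age < 145` middle;
`age < 66` late — boundary ownership is a convention the source
description leaves open), requiring at least 3 points per stage, with
two-sided p from the t distribution on `n − 2` df. **These p-values are
nominal**: both the rate and the DD series are autocorrelated along the
node-age grid, so the effective sample size is smaller than `n` and the
p-values are anti-conservative. The end-to-end null test therefore checks
what the method can honestly promise — that with Brownian traits, a single
smooth rate process and independent climate, the stage correlation
estimates are centred on zero and sign-balanced — rather than uniformity
of the nominal p-values, which does not hold under autocorrelation.

## Synthetic data: what it emulates, and what it does not

The generators provide every pipeline input with known ground truth.
`simulate_bd_tree()` is a forward Gillespie birth–death simulation started
from two crown lineages, stopped at a target extant tip count (at the
instant the count is reached, giving the classic Yule waiting-time law for
the crown age) or at a fixed crown span (conditioning on both crown
lineages surviving so the reconstructed crown equals the requested span);
whole-clade extinction is handled by seeded rejection, capped at 1,000
attempts. Climate series are piecewise-linear trends — sketching the last
200 Myr: cooling ΔT, O₂ rising ~16→21%, CO₂ falling ~2000→400 ppm — plus
Gaussian noise with an exponential (CAR(1)) autocorrelation kernel, the
same kernel the GLS fitter assumes, so the fitted model is exactly
realisable. `simulate_study_inputs()` assembles the full bundle at the
package's study conditions: 80 tips, crown rescaled to ~195 Ma, Brownian
body sizes with λ = 1 and per-tip SE 0.05 on the `ln(10×mm)` scale, ~20
posterior-style configurations around a slowly accelerating background
process, and a node-age warp `T(age/T)^0.55` giving the early-burst
node-age profile of a clade that radiated early — without the warp a
constant-rate tree leaves the pre-145 Ma stage almost empty of nodes,
which no early-radiating study system does.

What the generators do *not* emulate: fossil or incomplete sampling,
trait-dependent diversification, multivariate traits, real climate
excursions (impacts, hyperthermals), or posterior uncertainty in the tree
itself. Passing tests therefore demonstrate the statistics are computed
correctly and are well calibrated under their own model — not that the
model assumptions hold for any particular empirical clade.

## Problem sizes and tolerances

The test suite runs at sizes chosen to make Monte-Carlo bounds sharp while
keeping the suite quick: exhaustive DTT enumeration on 4–8-tip trees (200
trait draws, agreement to 1e-10); null calibration on a 100-tip tree with
200 replicates; λ recovery on 200-tip trees with 50 replicates per
condition; GLS recovery at n = 60 with 100 replicates at signal-to-noise
2. Monte-Carlo assertions use 3–5 standard-error bounds computed from the
replicates themselves, never fixed magic margins. Likelihoods are
validated against a dense multivariate-normal oracle, `phytools` (λ) and
`nlme` (CAR(1) GLS) serve as independent cross-implementations, and exact
identities (scale invariance, weight normalisation, left-step MDI algebra)
are asserted at 1e-12.

## Known limitations

* Nominal staged-correlation p-values under autocorrelation, as above.
* The DTT null band is pointwise; simultaneous envelopes would be wider.
* Extinction is constant per rate process; a time-varying μ hook is not
  implemented.
* The λ search is bounded to [0, 1]; values above 1 (possible on some
  trees) are not considered, matching standard practice.
* GLS standard errors ignore the uncertainty in φ.
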