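---
title: "Comparing survey protocols on detections and cost: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing survey protocols on detections and cost: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapcost)
```

`trapcost` compares wildlife survey protocols on detection effectiveness
and on cost, using a squamate case study: ten ~100 m heathland transects
surveyed concurrently by camera traps (74 days) and by two
labour-intensive methods — artificial refuges and pitfall traps — over four
4-day sub-surveys (16 days). Seven protocol variants arise by method and
duration: `All-74`, `CT-74`, `All-16`, `CT-16`, `LI` (= AR ∪ PF), `AR`,
`PF`. This vignette documents the statistical model, the data
reconstruction, the cost model, the numerical choices, and what the
package's validation does and does not demonstrate.

## The data and their reconstruction

The case study publishes two tables, both shipped as CSV fixtures: per
species, the *number* of transects (0–10) at which it was detected under
each protocol; and per protocol, the cost components of one survey. The raw
species × transect × method incidence is not published, so the per-transect
richness response `s_ij` cannot be read off directly.

`reconstruct_incidence()` therefore builds one *canonical* incidence cube
consistent with every printed count. The protocol structure constrains it
strongly: writing `|X|` for a species' transect-set size under method `X`,
the unions give `|AR ∩ PF| = AR + PF − LI`, `|CT-74 ∩ LI| = CT-74 + LI −
All-74` and `|CT-16 ∩ LI| = CT-16 + LI − All-16` by inclusion–exclusion, so
every valid reconstruction shares all pairwise overlap sizes; only *which*
transects carry them is undetermined. The canonical choice processes
species in table order and, at each selection, prefers transects in
ascending order of the running total of detections already assigned (ties
broken by ascending transect index). This is deterministic and spreads
detections evenly across transects — a neutral convention given that the
published counts carry no information about transect identity beyond the
marginals. Validation enforces the count-range and union inequalities per
species, plus the joint camera/LI overlap condition
`CT-16 − All-16 ≤ CT-74 − All-74` (required so the 16-day camera layer can
nest inside the 74-day layer; it is not implied by the per-union
inequalities alone). Users with real incidence data can bypass the
reconstruction entirely via `read_incidence()`.

The choice of a deterministic reconstruction (rather than, say, averaging
over random feasible realizations) keeps the pipeline reproducible and
auditable; its effect on results is limited because the model's response —
per-transect richness — depends on the reconstruction only through how
detections cluster across transects, and the even-spreading rule is the
least-clustered choice. The acceptance checks on posterior quantities
carry tolerances that allow for this reconstruction non-uniqueness.

## The detection-effectiveness model

Richness counts are modelled hierarchically:

$$s_{ij} \sim \text{Poisson}(\lambda_{ij}), \qquad
\ln \lambda_{ij} = \eta_i + \gamma_j,$$
$$\gamma_j \sim \mathcal N(0, \theta^2), \qquad
\theta \sim \text{Uniform}(0, 100),$$

where `eta_i` is protocol *i*'s log detection rate at a typical transect
and `gamma_j` a transect random effect. Two modelling decisions deserve
note:

* **Parameterization.** The model is conventionally written with a global
  intercept plus a per-protocol effect, each with a vague
  Normal(0, 1e12) prior — but only their sum is identified, and sampling
  both produces unidentified random walks that wreck convergence
  diagnostics. The default `protocol_intercepts` parameterization samples
  `eta_i` directly; a `corner_constraint` mode (first protocol as
  reference) is available in `model_spec()` for comparison, and recovers
  the same rates.
* **Shared scale.** One observation per transect per protocol cannot inform
  a *per-transect* variance, so a single shared `theta` is used — the
  standard hierarchical random-effect standard deviation with a
  Uniform(0, 100) prior, which is what the precision-parameterized BUGS
  idiom `N(0, theta^-2)` denotes.

Protocol comparison uses the typical-transect rate
`lambda_i = exp(eta_i)` (transect effect zero), not a posterior-predictive
count: superiority probabilities are fractions of paired posterior draws
with `lambda_x >= lambda_y`, ties counting toward "at least as many"
(measure-zero for continuous draws), computed by default from 10,000
pooled draws.

## Sampler and convergence

`run_mcmc()` is a Metropolis-within-Gibbs sampler: scalar random-walk
Metropolis updates for each `eta_i`, each `gamma_j` and `theta`, in fixed
scan order. The conditional densities reduce to
`s_i. eta_i − e^{eta_i} Σ_j e^{gamma_j}` (and symmetrically for `gamma_j`)
plus priors, so each update is O(1) given cached exponential sums.

Numerical choices:

* **Initialization.** `eta_i = log((row total + 0.5)/n_transects)` (the
  0.5 guards empty protocols), `gamma_j = 0`,
  `theta = min(1, upper/2)` — inside the prior support even for tiny
  user-set bounds.
* **Adaptation.** Every 50 burn-in iterations each step size is scaled by
  `exp(acceptance − 0.35)` (clamped to [1e-4, 10]), targeting the 20–50%
  acceptance band for scalar updates; steps are frozen after burn-in so
  the retained chain is a valid Markov chain.
* **Defaults.** Two chains of 12,000 iterations, half burn-in — 12,000
  pooled retained draws, exceeding the 10,000 used for superiority and
  cost-effectiveness summaries. A run below the retained target warns.
* **Reproducibility.** The run seed deterministically spawns per-chain
  seeds; identical configurations give bit-identical draws.

Convergence is assessed per parameter by the Gelman–Rubin potential scale
reduction factor, `sqrt(((n−1)/n · W + B/n)/W)` with `W` the mean
within-chain variance and `B/n` the variance of chain means; the fit's
`converged` flag requires every PSRF < 1.05 (chains with numerically zero
within-chain variance are flagged degenerate rather than silently passed).
A unit test cross-checks the implementation against `coda::gelman.diag`,
which differs only by a small-sample degrees-of-freedom correction.
Effective sample sizes use the initial-positive-sequence autocorrelation
estimator.

The sampler's correctness is anchored by two oracles: the log joint
density is tested against an independently coded term-by-term summation,
and a single-cell model with the transect effect pinned (tiny `theta`
bound) reproduces the conjugate Gamma posterior — with a prior flat on the
*log* rate, `s` detections give a Gamma(`s`, 1) rate posterior, which the
vague-normal prior approaches. Parameter recovery on synthetic data is
described below.

## The cost model

One survey's cost profile has equipment `E` (a sunk cost; a fraction `r` —
the replacement rate, RoR — is re-purchased each repeat survey), per-survey
vehicle `V`, consumables `C` and labour `h·L`, plus one-off deployment
costs `h·l + v` for digging in pitfall traps and placing refuges. Total and
marginal cost follow the displayed formulas in the README. Evaluation is
exact; `total_cost(m+1) − total_cost(m) = marginal_cost` holds to floating
point, and is tested over randomized profiles.

Scenario grids: the full sweep is `r ∈ {0, 0.01, …, 0.30}` ×
`h ∈ {0, 1, …, 55}` (1,736 scenarios; $55 is just under a senior casual
research assistant's hourly rate, 0 models an all-volunteer crew). The
endpoint `r = 0` is included — the formal constraint `0 < r < 1` is
relaxed at the boundary because the published sweep starts at 0%. The
"realistic" sub-grid reads "RoR < 10% and wage > $10" on the discrete grid
as `r ≤ 0.09, h ≥ 11`, the only consistent strict reading at these step
sizes. Grid summaries use the population (divide-by-N) standard deviation:
the grid *is* the population of scenarios considered. Because the marginal
cost is affine in `(r, h)`, the grid mean equals the formula at the grid
means and the SD has the closed form
`sqrt(E² Var(r) + L² Var(h))` on an independent rectangular grid — both
are regression tests.

## Cost-effectiveness

`cost_per_species()` divides a protocol's mean marginal cost over a grid by
each posterior rate draw; the summary is the draw mean and equal-tailed
95% quantile interval (the BUGS-era default; not HPD). Only detection
uncertainty enters the default interval — the scalar-cost treatment
reproduces the scale of the published intervals. Since `1/lambda` is
convex, the mean cost per species strictly exceeds cost divided by mean
rate (tested). An optional `propagate_cost = TRUE` mode crosses every grid
scenario with every rate draw, widening the intervals — a sensitivity
analysis for users who want cost-scenario spread propagated; the published
values cannot distinguish the two modes, so the simpler is the default.

## The synthetic-data generator

Two generators make every stage testable without field data, with defaults
fixed at the study's conditions:

* `simulate_richness()` forward-simulates the hierarchical model:
  default log-rates are `study_log_rates()` — the packaged table's column
  sums over 10 transects, i.e. rates 6.0, 5.3, 4.3, 3.4, 3.0, 2.3, 1.6 —
  with `theta = 0.3`, a moderate transect heterogeneity (±35% rate
  variation across transects, about what patchy heath cover would
  produce); the study itself does not report a fitted scale, and the
  fixture data turn out to be consistent with a much smaller one.
* `simulate_incidence()` generates raw incidence with the assumed
  structure: species × transect occupancy (probability 0.8), then
  independent per-method detections given presence — CT-74 0.65, CT-16 by
  thinning CT-74 at 0.65 (which enforces the camera nesting by
  construction), AR 0.30, PF 0.25 — matched once to the fixture's per-cell
  prevalences (0.53, 0.34, 0.23, 0.16). Derived protocol columns are
  unions, so generated tables are always feasible for
  `reconstruct_incidence()`; marginal-exactness of the reconstruction is
  property-tested over ten thousand generated tables.

What passing these tests shows — and does not. The generators emulate the
model the analysis assumes: Poisson richness, exchangeable transects,
method-independent detections given presence. Real squamate data violate
some of this (behavioural differences make camera and refuge detections
non-independent; weather drives shared detection shocks; transects are
spatially structured). Parameter recovery on synthetic data therefore
validates the *computation*, not the model's adequacy for any particular
field system.

Validation sizes (the package's choices): parameter recovery runs 50
replicate simulate-and-refit cycles at the study's transect count with the
headline rate contrast (5.3 vs 3.0) and shortened chains (2 × 3,000
iterations), asserting median absolute log-rate error below 0.15 and
roughly nominal 95% interval coverage; protocol separation (rate 10 vs 3)
must exceed 0.95 superiority.

## Known limitations and non-reproducible published figures

* Two published numbers are not derivable from the published inputs and
  are deliberately not targeted: the realized **2,492 camera-trap-days**
  (the per-camera outage schedule behind it is unpublished; the design
  figure is 4 × 10 × 69 = 2,760, and `survey_effort()` takes outages as an
  explicit adjustment), and the **$30,325** upper first-survey cost for
  CT-16 (the published rounded 51 labour hours give $30,303; the original
  evidently used unrounded hours). Both are kept as documented
  discrepancies.
* The incidence reconstruction is one canonical realization; quantities
  that depend on within-transect clustering beyond the marginals inherit
  that convention.
* The model has no covariates, no occupancy/detection-probability layer,
  and no model-comparison machinery — protocol rates and their contrasts
  are the entire estimand.
* Costs are a label-level currency (AUD as published), with no
  discounting, travel-distance or accommodation modelling (the study's
  best-case costing deliberately excludes them).
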