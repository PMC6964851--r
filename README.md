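# trapcost

Which wildlife survey protocol should you run: a long camera-trap
deployment, or repeated visits with labour-intensive gear such as artificial
refuges and pitfall traps? `trapcost` answers that question on two axes —
how many species a protocol detects per transect, and what it costs to keep
running — and combines them into cost per species detected.

The package ships a complete squamate (snake and lizard) case study: a
74-day camera-trap survey run concurrently with four 4-day
artificial-refuge/pitfall-trap surveys on ten ~100 m heathland transects,
yielding seven protocol variants (`All-74`, `CT-74`, `All-16`, `CT-16`,
`LI`, `AR`, `PF`). All inputs are small plain-text tables packaged under
`inst/extdata/`; every published headline number is recomputable from them.

## The model

**Detection effectiveness.** The number of species detected by protocol
*i* at transect *j* is modelled as

```
s_ij ~ Poisson(lambda_ij),   ln(lambda_ij) = eta_i + gamma_j
gamma_j ~ Normal(0, theta^2),   theta ~ Uniform(0, 100)
```

with a vague Normal(0, 1e12) prior on each protocol log-rate `eta_i`
(the sum of a global intercept and a protocol effect; only the sum is
identified, so it is sampled directly). The model is fitted by a
Metropolis-within-Gibbs sampler (scalar random-walk updates per parameter,
step sizes adapted during burn-in only), run as two chains with half of
each chain discarded as burn-in, and checked with the Gelman–Rubin
potential scale reduction factor (all PSRF < 1.05). Pairwise protocol
comparisons are posterior superiority probabilities: the fraction of
paired draws with `lambda_x >= lambda_y`.

**Cost.** Running protocol *i* for *m* surveys costs

```
T_i(m) = E_i (1 + r (m - 1)) + m (V_i + C_i + h L_i) + h l_i + v_i
M_i    = dT/dm = r E_i + V_i + C_i + h L_i
```

where `E` is equipment, `V` vehicle, `C` consumables, `L` labour hours,
`l`/`v` one-off deployment labour/vehicle, `r` the equipment replacement
rate and `h` the hourly wage (AUD). The marginal cost `M_i` is swept over a
replacement-rate × wage grid (1% steps from 0–30% crossed with $1 steps
from $0–$55; the "realistic" sub-grid is r ≤ 0.09, h ≥ 11) and its grid
mean, divided draw-by-draw by the posterior rate `lambda_i = exp(eta_i)`,
gives the cost-per-species posterior with equal-tailed 95% credible
intervals.

Because only per-species *counts* of transects with detections are
published, `reconstruct_incidence()` builds a canonical species × transect
× method incidence cube whose protocol marginals match every printed count
exactly (deterministic, even-spreading allocation; the camera/LI overlap
sizes are forced by inclusion–exclusion, only transect identities are a
convention).

## Worked example

```r
library(trapcost)

table <- load_detection_table()          # 10 species x 7 protocol counts
cube  <- reconstruct_incidence(table)    # canonical incidence realization
s     <- richness_matrix(cube)           # species detected per protocol x transect

fit <- run_mcmc(s, config = mcmc_config(seed = 1))
fit
#> Hierarchical Poisson richness model fit
#>   protocols: All-74, CT-74, All-16, CT-16, LI, AR, PF
#>   chains: 2  iterations/chain: 12000  pooled retained draws: 12000
#>   max PSRF: 1.01 (converged, all < 1.05)

sup <- superiority_matrix(pairwise_superiority(fit))
round(sup["CT-74", c("LI", "AR", "PF", "All-16")], 3)
#>     LI     AR     PF All-16
#>  0.996  1.000  1.000  0.866
```

So the 74-day camera survey detects at least as many species per transect
as the combined labour-intensive methods with posterior probability ~0.99,
and beats even the all-methods 16-day protocol ~87% of the time.

```r
profiles <- load_cost_profiles()
scenario_summary(profiles, scenario_grid("full"))
#> # A tibble: 7 x 5
#>   protocol grid  n_scenarios   mean    sd
#> 1 All-74   full         1736 13137. 4460.
#> 2 CT-74    full         1736  6015. 2468.
#> ...

cost_effectiveness(fit, profiles, scenario_grid("realistic"),
                   protocols = c("CT-74", "LI"))
#>   protocol grid      mean_marginal_cost  mean ci_lower ci_upper
#> 1 CT-74    realistic               3449   665      505      867
#> 2 LI       realistic               8295  2858     1989     4070
```

Under realistic running conditions (equipment losses under 10%, paid field
staff), a repeat camera survey costs about $665 per squamate species
detected per transect (CI ~505–867), roughly a quarter of the
labour-intensive methods' ~$2,860 (CI ~1,990–4,070) — camera trapping is
the clear cost-effectiveness winner despite its large up-front equipment
outlay ($27,482 for the first survey versus $4,700 at volunteer wages).

`run_survey_analysis(out_dir, seed)` runs the whole pipeline and writes the
draws, convergence report, superiority matrix, cost summaries and
cost-effectiveness tables as CSV/JSON. `autoplot()` methods cover the
superiority heatmap and the cost-per-species interval plot;
`plot_total_cost()` draws total-cost trajectories against survey count.

## Vignette

`vignettes/trapcost-methods.Rmd` documents the model and its assumptions,
the incidence reconstruction, sampler design and convergence checks, the
cost model's scenario grids, the synthetic-data generator, and known
limitations (including two published figures that are not derivable from
the published inputs).
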