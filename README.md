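# collmix

Bayesian N-mixture models for estimating bird and bat collision
mortality at wind energy turbines from carcass searches, covariates of
the collision rate, and imperfect-detection parameters.

## The problem

Morning carcass searches below wind turbines undercount the animals
killed by the rotor blades: a carcass is recovered only if it fell into
the searched area (probability *a*), was not removed by scavengers
before the search (daily persistence *s*), and was then actually seen
(searcher efficiency *f*).  The conventional remedy — dividing or
Bayes-inverting the total count through a composite detection
probability *p* (the "corrected count") — yields wide intervals when few
carcasses are found, and gives no handle on *when* collisions happen.

collmix combines the carcass counts with nightly covariates (acoustic
bat activity recorded at the nacelle, wind speed) in a hierarchical
mixture model, so that collision-rate information flows between nights
and turbines.  The package targets ecologists and consultants doing
post-construction fatality monitoring; fitted models also support
predicting collision numbers for turbines or nights *without* searches,
the ingredient needed for curtailment algorithms.

## The model

Nightly collisions at turbine *i* are latent Poisson counts,

```
N_it ~ Poisson(lambda_it),
log lambda_it = alpha0 + alpha1*zA_it + alpha2*zW_it + alpha3*zW_it^2,
```

with `zA`, `zW` the z-standardized activity and wind speed.  Two
observation models link collisions to found carcasses `c_it`:

* **one-level** — `c_it ~ Binomial(N_it, p_i)`, with a moment-matched
  Beta prior on `p_i` built from its field point estimate and 95% CI;
* **three-level** — an explicit chain `fallen ~ Binomial(N, a_i)`;
  `available_t = remaining_{t-1} - found_{t-1} + fallen_t`;
  `remaining ~ Binomial(available, s_i)`;
  `found ~ Binomial(remaining, f_i)`, in which carcasses missed at one
  search stay available for the next (found ones are removed by the
  searcher).

Posteriors are sampled by a Metropolis-within-Gibbs scheme with exact
conditional updates for the latent counts (including a collapsed Gibbs
update of the fall-in counts and a kill-time shift move that is
essential for mixing across kill-night allocations; the inner loops are
in C++).  The conventional corrected count — `N - C ~
NegBinomial(C + 1, p)` under a flat prior, with Monte-Carlo propagation
of the uncertainty in `p` — is included as the comparator, along with a
full simulator for bias/precision studies and posterior predictive
checks.  See the vignette `vignettes/collision-mixture-models.Rmd` for
the methods in detail.

## Worked example

The package bundles the published per-turbine detection table from a
two-year carcass-search study at 30 German wind turbines (12 sampled in
2007, 18 in 2008, daily searches July–September).

```r
library(collmix)
library(dplyr)

det <- example_detection_table()
summarize_dataset(det)
#> # A tibble: 2 × 5
#>    year n_turbines total_carcasses turbine_nights mean_detection
#>   <int>      <int>           <int>          <int>          <dbl>
#> 1  2007         12              22            473          0.586
#> 2  2008         18              35           1225          0.612
```

22 carcasses were found over 473 turbine-nights in 2007, 35 over 1225 in
2008, at mean detection probabilities of 0.59 and 0.61.  The pooled
corrected count for 2008 inverts the 35 found carcasses through an
effort-weighted Beta prior on detection:

```r
set.seed(1)
det |>
  filter(year == 2008) |>
  estimate_corrected_per_turbine(mode = "pooled", n_draws = 1e5)
#> # A tibble: 1 × 6
#>       C  mean median lower upper  mode
#>   <int> <dbl>  <dbl> <dbl> <dbl> <int>
#> 1    35  57.3     55    42    84    51
```

So the study's 35 found carcasses imply roughly 57 actual collisions
(95% interval 42–84): detection failures roughly halve the count.  From
the fitted collision coefficients of that season, the wind speed at
which the collision rate peaks (at constant activity) is

```r
fitted <- reported_coefficients() |> filter(year == 2008, model == "three_level")
wind_at_max_rate(
  collision_coefficients(fitted$alpha0, fitted$alpha1, fitted$alpha2, fitted$alpha3),
  wind_mean = 5.5, wind_sd = 1.8, digits = 1
)
#> [1] 3.5
```

3.5 m/s — collision risk is concentrated at moderate wind, which is what
makes raised cut-in speeds effective.

The nightly field records behind the fitted models are not published, so
model fitting is demonstrated on simulated data (the simulator
reproduces the study's generative design):

```r
cfg <- sim_config(n_turbines = 6, nights_per_turbine = 60, seed = 42)
rep <- simulate_replicate(cfg, 1)
rep
#> <sim_replicate> 6 turbines x 60 nights: 18 collisions, 12 carcasses found

fit <- fit_three_level(rep,
  cfg = mcmc_config(n_iterations = 30000, burn_in = 15000, thin = 10, seed = 1))
tidy(fit)
#> # A tibble: 4 × 6
#>   term   estimate std.error conf.low conf.high  rhat
#>   <chr>     <dbl>     <dbl>    <dbl>     <dbl> <dbl>
#> 1 alpha0   -4.86      1.26    -8.18     -3.04   1.02
#> 2 alpha1    0.681     0.156    0.378     0.986  1.00
#> 3 alpha2   -4.69      2.57   -11.8      -0.626  1.03
#> 4 alpha3   -2.69      1.22    -5.66     -0.790  1.03
mortality_summary(fit, "total")
#> # A tibble: 1 × 4
#>    mean median lower upper
#>   <dbl>  <dbl> <dbl> <dbl>
#> 1  16.5     16    12    23
```

The 12 found carcasses came from 18 simulated collisions; the posterior
total (mean 16.5, 95% CrI 12–23) recovers the truth, and the credible
intervals for the generating coefficients (−4.1, 0.5, −2.9, −1.3) cover
them.  `autoplot(fit)` draws the coefficient intervals,
`posterior_predictive_check(fit)` the count-frequency calibration table,
and `predict_new()` the predictive collision total for new covariates.

File-based pipelines use the `run_*()` commands (`run_fit`,
`run_corrected`, `run_simulate`, `run_predict`, `run_ppc`,
`run_evaluate`) or the dispatcher script installed at
`inst/cli/collmix.R`; all outputs carry a header line with the package
version, seed and input checksums.

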