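# opennmix

Open-population (dynamic) N-mixture models for repeated point-count surveys,
with density-dependent growth rates, WAIC model selection and spatial
residual diagnostics — for population ecologists asking whether local growth
at a range margin rises with density (an Allee effect, e.g. from scarce
social cues) or falls with it (negative density dependence), while
accounting for climate and imperfect detection.

## The model

For site $i$, year $t$ and within-survey period $j$:

```
log(psi_i)        = b0_psi + b1_psi * CLIMATE_i          N_i1 ~ Poisson(psi_i)
log(lambda_i,t-1) = b0_l + b1_l*CLIMATE_i + b2_l*TREATMENT_it
                     + b3_l*DENSITY_i,t-1 [+ quadratics, interaction]
                                                          N_it ~ Poisson(N_i,t-1 * lambda_i,t-1)
logit(p_ijt)      = b0_p + b_wind*WIND + b_noise*NOISE
                     + b_date*DATE + b_time*TIME           y_ijt ~ Binomial(N_it, p_ijt)
```

`DENSITY` is the latent abundance itself (raw count units), so `b3_l < 0` is
a per-individual decrement of log growth rate — negative density
dependence — and `b3_l > 0` would indicate an Allee effect. `CLIMATE` is the
first principal component of site temperature/precipitation normals
(cooler-and-wetter sites negative). Extinction is absorbing: no immigration.

The package provides an exact marginal likelihood (forward algorithm over
the latent states, `O(T K^2)` per site), a Metropolis-within-Gibbs sampler
with explicit latent abundances plus a collapsed intercept move for the
weakly identified abundance–detection ridge, the nine-model WAIC comparison
set, Moran's I permutation tests of per-year residuals, and a synthetic-data
generator reproducing the 71-site playback-experiment design it targets.

## Worked example

```r
library(opennmix)

sim <- simulate_reference(seed = 7)   # 71-site grid, 4 years x 4 periods
sim
#> <nmix_sim> seed 8; latent totals by year: 10, 9, 7, 2
#> <pcount_data> 71 sites x 4 years x 4 periods; 69 birds detected; 18 treated site-years

fit <- run_mcmc(sim$data, "lambda ~ climate + treatment + density",
                config = mcmc_config(seed = 1), pointwise = FALSE)
posterior_summary(fit)
#>    Parameter             Mean     SD `Lower CI` `Upper CI`
#>  1 psi_(Intercept)    -3.99    0.926    -6.00       -2.44
#>  2 psi_climate        -2.35    0.649    -3.70       -1.20
#>  3 lambda_(Intercept) -0.0582  1.16     -2.50        2.07
#>  4 lambda_climate     -0.900   0.717    -2.33        0.444
#>  5 lambda_treatment   -0.0648 10.1     -19.9        19.6
#>  6 lambda_density     -0.959   0.410    -1.84       -0.221
#>  7 p_(Intercept)       0.483   0.278    -0.0862      1.02
#>  ...
mean(fit$draws[, "lambda_density"] < 0)
#> [1] 1
```

The density coefficient is negative with posterior probability 1: on these
simulated data growth rate falls as density rises (no Allee effect), even
though only ~10 territories exist in year 1. The treatment coefficient
stays at its prior (sd 10) because no birds settle at treated sites — the
data carry no information about it, and the summary shows that honestly.
Detection converts to interpretable scales with

```r
p1 <- plogis(0.483)                  # per 2.5-min period: 0.62
cumulative_detection(p1, J = 4)      # whole 10-min survey: 0.979
```

and per-year spatial diagnostics come from

```r
residual_scan(fit, n_perm = 499, seed = 2)
#>   year        I expected_I p_value n_sites
#> 1 2014 -0.0169     -0.0143   0.806      71
#> 2 2015 -0.0113     -0.0143   0.788      71
#> 3 2016 -0.0135     -0.0143   0.96       71
#> 4 2017 -0.0286     -0.0143   0.012      71
```

— no evidence of residual spatial autocorrelation in the first three years;
the marginal final year has two surviving birds, about the resolution limit
of the test. `tidy()`, `glance()` and `autoplot()` methods give broom-style
summaries and ggplot figures for fits, model tables and residual fields;
`select_models()` fits the nine-model set and returns the ranked
WAIC/weight table; `run_pipeline()` drives
simulate → fit → select → diagnose from one config with a JSON manifest.

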