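# mobidence

Migration-adjusted small-area disease incidence mapping.

Cancer surveillance systems built on household registration count a case
where a person is *registered*, while the person's actual risk and the
population truly at risk live where people *reside*. In a country with
tens of millions of internal migrants this gap biases registry-based
incidence: provinces receiving migrants have their case burden
underestimated and their rates overestimated, and sending provinces the
reverse. `mobidence` implements the full estimation chain needed to
correct county-level incidence for this bias:

1. **Covariate screening** — single-predictor Poisson AIC ranking, a
   greedy pairwise-correlation filter (|r| > 0.8), and iterative
   variance-inflation-factor exclusion (VIF > 10).
2. **Bayesian geostatistical smoothing** — counts in registry counties
   `i` follow `y_i ~ Poisson(E_i exp(beta_0 + x_i' beta + u(s_i)))`
   where `E_i` is the age-schedule expected count and `u` is a Matérn
   (nu = 1) Gaussian field represented through the SPDE finite-element
   approximation as a Gaussian Markov random field with sparse
   precision `Q = tau^2 (kappa^4 C + 2 kappa^2 G + G C^-1 G)`.
   Inference is a from-scratch nested-Laplace scheme: Newton
   optimization of the latent posterior at every node of a
   (range x partial-sill) grid, Gaussian approximation at the mode,
   grid weights proportional to prior times Laplace marginal
   likelihood, and posterior marginals as grid mixtures. Rates are
   predicted for *all* counties, registry members or not, with DIC,
   WAIC, marginal log-likelihood, credible-interval validation, 5-fold
   cross-validation and a sensitivity suite (spatial vs non-spatial,
   leave-one-covariate-out, pinned hyperparameters).
3. **Migration adjustment** — provincial net migrants are the resident
   minus household-registered population; migrant stocks
   `M[origin, destination, age, stratum]` carry expected cases
   `M * rate / 100,000` priced by an age-specific schedule, moved from
   the origin's registered count to the destination's resident count.
   Difference tables report cases, crude rates, `Diff`, `Diff%` and the
   emigrating/immigrating footer; indirect standardization converts
   observed counts to SIR and ASIR against a standard population.
4. **Cluster detection** — global Moran's I with permutation tests and
   local (LISA) HH/LL/LH/HL classification under queen-contiguity
   row-standardized weights, plus excess-risk ratios and per-province
   cluster summaries.

Because real registry microdata are not distributable, the package
ships a first-class synthetic-data generator that reproduces the
statistical structure of the problem — a province-partitioned county
lattice, lognormal county populations with a tapering male age pyramid,
working-age-skewed inter-provincial migrant stocks that conserve
national person-years exactly, spatially smoothed standardized
covariates with optional collinear pairs, a latent Matérn risk field,
and Poisson registry counts on partial coverage — together with the
ground truth needed for parameter-recovery testing.

## Worked example

```r
library(mobidence)

geo <- generate_geography(n_provinces = 4, counties_per_province = 50,
                          urban_fraction = 0.4, seed = 1)
geo <- simulate_populations_and_migration(geo, migrant_rate = 0.15, seed = 2)
geo <- simulate_covariates(geo, n_covariates = 4, n_collinear_pairs = 1,
                           spatial_corr = 0.3, seed = 3)
truth <- make_ground_truth(geo, beta = c("(Intercept)" = 0, cov1 = 0.3),
                           spatial_range = 3, spatial_sd = 0.4, seed = 4)
sim <- simulate_registry_cases(geo, truth, registry_fraction = 0.5, seed = 5)
co <- sim$counties

reg <- which(co$is_registry)
scr <- screen_covariates(co$observed_cases[reg], co$expected_hrp[reg],
                         co[reg, paste0("cov", 1:4)])
scr
#> screen_report: 4 candidates -> 3 retained
#> retained (AIC order): cov1, cov3, cov4
#> dropped by correlation:
#>   covariate partner     r
#> 1      cov2    cov1 0.961

mesh <- build_mesh(cbind(co$x, co$y), max_edge = 2, boundary_extension = 3)
fit <- spde_fit(co$observed_cases, co$expected_hrp,
                X = as.matrix(co[, scr$retained]), mesh = mesh)
fit
#> spde_fit (poisson, spatial): 100 observations, 200 counties, 49 hyper grid points
#>          term      mean      sd     q025   q975
#> 1 (Intercept) -0.082776 0.10223 -0.28441 0.1267
#> 2        cov1  0.323079 0.06571  0.19404 0.4520
#> 3        cov3  0.048037 0.06613 -0.08106 0.1782
#> 4        cov4  0.008739 0.05943 -0.10798 0.1252
#> posterior mean range 2.462, field sd 0.469; MLL -323.611

validate_coverage(fit)$coverage   # 0.97
model_criteria(fit, seed = 6)     # DIC 571.8, WAIC 562.9, ...
```

The screening funnel dropped the constructed collinear partner
(`cov2`, r = 0.96 with `cov1`) and the fit recovered the true covariate
effect (0.32, 95% BCI 0.19–0.45, truth 0.30), the field sd (0.47,
truth 0.40) and the correlation range (2.5, truth 3), while 97% of the
registry counts fell inside their 95% credible intervals.

`run_pipeline(default_config(seed = 1))` chains everything — simulate,
screen, fit, adjust, standardize, cluster — and writes stamped CSV/JSON
outputs (`counties.csv`, `screen_report.csv`, `fit.json`,
`county_rates.csv`, `table1.csv`, `table2.csv`, `clusters.csv`,
`summary.csv`). A thin command-line wrapper lives at `exec/mobidence`
(`run`, `simulate`, `screen`, `cluster` subcommands).

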