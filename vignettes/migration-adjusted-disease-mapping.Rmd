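---
title: "Migration-adjusted small-area incidence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Migration-adjusted small-area incidence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobidence)
```

# The estimation problem

Registry-based cancer surveillance in a household-registration system
measures incidence on the *household-registered population* (HRP):
cases and denominators are attached to the province where a person's
registration is held. The *resident population* (RP) — where people
actually live — can differ from the HRP by tens of millions of
inter-provincial migrants, most of them working-age men. Incidence of
an old-age disease such as prostate cancer is then distorted twice:
inflow provinces have their resident case burden underestimated and
their crude rates diluted by young in-migrants, while outflow provinces
show the opposite. `mobidence` estimates county-level incidence from a
partial registry network, transfers expected cases between provinces
according to migrant stocks, and summarizes the corrected geography of
risk.

# The spatial model

For registry county $i$ with male population age structure $n_{ia}$ and
a baseline age schedule $s_a$ (per 100,000), the expected count is
$E_i = \sum_a n_{ia} s_a / 10^5$ and

$$y_i \sim \mathrm{Poisson}\!\left(E_i \exp(\beta_0 + x_i'\beta + u(s_i))\right),$$

with standardized covariates $x_i$ and a zero-mean Matérn ($\nu = 1$)
Gaussian field $u$. The field is represented by the stochastic-PDE
finite-element construction: a Delaunay triangulation over the county
centroids plus a boundary ring, lumped mass matrix $C$, stiffness
matrix $G$, and sparse precision

$$Q = \tau^2\left(\kappa^4 C + 2\kappa^2 G + G C^{-1} G\right),
\qquad \kappa = \sqrt{8}/\rho,\quad
\tau = \left(\sigma_u\,\kappa\sqrt{4\pi}\right)^{-1},$$

so $\rho$ is the distance at which correlation falls to about 0.1 and
$\sigma_u$ the marginal sd. A barycentric projector $A$ maps mesh
vertices to county centroids.

Inference follows the nested-Laplace recipe rather than MCMC. Over a
fixed log-spaced grid of $(\rho, \sigma_u^2)$ values (default
$7 \times 7$ over $\rho \in [1, 10]$, partial sill $\in [0.01, 5]$),
each grid point gets a Newton optimization of the joint latent vector
$(\beta, u)$ (line search; convergence at gradient $\infty$-norm
$< 10^{-6}$; at most 100 iterations), a Gaussian approximation at the
mode, and a weight proportional to the hyper prior times the
Laplace-approximated marginal likelihood (including the log-grid cell
measure). Posterior marginals of every fixed effect and every county
log relative risk are mixtures of the per-grid-point Gaussians;
percentiles come from numerical inversion of the mixture CDF. In the
Gaussian-likelihood limit the Laplace approximation is exact, which the
test suite exploits as a closed-form oracle; with the field switched
off the posterior mode must match an independently coded penalized
IRLS solver, a second oracle.

## Priors and numerical choices

* Penalized-complexity-style hyper priors:
  $P(\rho < \rho_0) = 0.5$ with $\rho_0 = 3$ grid units, and
  $P(\sigma_u > 1) = 0.1$. Fixed effects get independent
  $N(0, 10^2)$ priors. These are weak at the scale of the data and are
  exposed through `spde_priors()`.
* The "partial sill" grid is interpreted as the field *variance*
  ($\sigma_u^2$), the geostatistical convention; `sill_is_variance =
  FALSE` switches to the sd scale.
* The Matérn smoothness is fixed at $\nu = 1$ ($\alpha = 2$), the
  standard two-dimensional SPDE choice.
* Mass lumping keeps $Q$ sparse; the price is a mesh-resolution-
  dependent inflation of the marginal variance (about +10% at mesh
  edges of $\rho/3$, vanishing under refinement), well inside the
  factor-of-two recovery tolerance used for hyperparameters.
* Hyperparameter grids are deterministic, so identical seeds reproduce
  identical fits bit for bit.

## Validation conventions

`validate_coverage()` checks observed registry counts against the 95%
credible interval of the *fitted count* $E_i \exp(\eta_i)$ — the usual
BCI validation of small-area disease-mapping fits, and the convention
under which a well-specified synthetic fit shows mean coverage near
0.94. The alternative `interval = "predictive"` adds Poisson
observation noise to linear-predictor draws; being an in-sample
posterior-predictive check it is conservative by construction
(empirical coverage near 1.0) and is provided for completeness rather
than calibration assessment.

DIC and WAIC are Monte-Carlo estimates from (by default) 1,000 draws
of the mixture approximation; the marginal log-likelihood is the
log-sum of the weighted Laplace evidences. Cross-validation stratifies
folds by province and scores held-out counties on predictive log score
and the RMSE of standardized incidence ratios. The sensitivity suite
refits without the field, with each covariate deleted in turn, and at
pinned hyperparameter values, reporting comparable DIC rows.

# Covariate screening

Candidates are ranked by single-covariate Poisson AIC (offset
$\log E_i$), then filtered greedily in rank order by pairwise
correlation ($|r| > 0.8$ drops the worse-ranked member), then by
iteratively recomputed VIF (largest VIF above 10 removed first). Rank
order first and iterative VIF recomputation make the funnel
deterministic and keep the best single predictors; the final model
choice remains a configuration decision, since predictive performance
and substantive interest cannot be formalized into the funnel.

# Migration adjustment and standardization

Provincial net migration is $RP(p) - HRP(p)$. A migrant stock entry
$M[i, j, a, s]$ (registered in $i$, resident in stratum $s$ of $j$, age
band $a$) carries $M \cdot r_a / 10^5$ expected cases. The removal leg
is always priced at the origin's age schedule — those cases are
embedded in the origin's registry-based estimate — and spread over the
origin's strata proportionally to its stratum case shares (no
stratum-of-origin information exists in the stock table). The addition
leg is priced by the `basis` argument: `origin` (default; the two legs
cancel and national totals are conserved exactly), `destination`
(migrants take on destination risk; totals are then not conserved when
schedules differ, the asymmetry real accounting of this kind
exhibits), or `national`. Province-level age schedules derive from a
national schedule scaled by the province-to-national crude-rate ratio,
a proportional-age-structure assumption.

Difference tables report HRP/RP cases, `Diff`, `Diff%` and crude rates
per province and stratum with an emigrating/immigrating footer
satisfying `immigrating - emigrating = national net difference`
identically. Indirect standardization prices the local age structure
at a standard schedule ($\mathrm{expected} = \sum_a n_a s_a/10^5$),
yielding $\mathrm{SIR} = \mathrm{observed}/\mathrm{expected}$ and
$\mathrm{ASIR} = \mathrm{SIR} \times \sum_a w_a s_a$; direct
standardization is out of scope because county age-specific case
counts are exactly what the registry network lacks.

# Spatial autocorrelation

Queen-contiguity, row-standardized weights (configurable), global
Moran's I with a one-sided permutation test
($p = (1 + \#\{I_{perm} \ge I_{obs}\})/(1 + N)$, default $N = 999$),
and local Moran statistics with conditional permutation (each county's
neighbors resampled from all other values), classified HH/LL/LH/HL by
the signs of the centered value and its lag, significant at an
uncorrected $\alpha = 0.05$. These conventions follow prevailing
disease-mapping practice; none is dictated by the method itself, and
all are arguments. The variable analyzed by the pipeline is the county
resident-population crude rate (model-based county cases scaled by the
province-stratum RP/HRP case ratio over RP denominators); the input
column is configurable.

# The synthetic-data generator

The generator is the package's study system, not a test fixture. It
emulates:

* a province-partitioned jittered county lattice (provinces are
  contiguous blocks; queen adjacency; jitter < 0.3 grid units so the
  SPDE distance unit stays interpretable);
* lognormal county male populations (sd 0.3 on the log scale) split by
  a male age pyramid flat to age 50 and tapering above;
* migrant stocks at a configurable share of national HRP (defaults:
  15% in the pipeline, in the region of the roughly one-quarter
  migrant share large registration systems report), flowing
  predominantly from the first half of provinces to the second,
  weighted toward ages 20–49 by `young_skew` (default 4), landing 80%
  urban, capped below 90% of any origin age-band population, and
  apportioned to counties by largest-remainder rounding so national
  person-years are conserved *exactly* in integers;
* standardized covariate surfaces, optionally neighbor-smoothed, with
  constructed near-collinear pairs (r about 0.97) to exercise the
  screening funnel;
* a latent Matérn field sampled through the same SPDE precision the
  fitter uses, and Poisson registry counts on a stratified partial
  registry (default 30% of counties).

What it does not emulate: real administrative geometry, registry
quality variation, age-specific covariate effects, temporal trends, or
survey-design noise in migrant stocks. Passing recovery and
calibration tests therefore demonstrates the estimator's correctness
under the model's own assumptions, not robustness to real-data
violations of them.

Default age bands are 5-year bands 0–4 … 85+; the baseline schedule is
prostate-cancer-like (near zero before 40, rising steeply afterwards).
The migrant age resolution is a parameter because administrative
sources differ in what they publish.

# Problem sizes used by the test suite

Simulation-based checks run at sizes chosen to be statistically
decisive while keeping the suite quick on a laptop: parameter recovery
and interval calibration use 20 replicates of 400 registry counties on
a 5 × 5 hyper grid (the recovery tolerance ±0.1 on the covariate
effect and a factor of two on hyperparameters, met in ≥ 80% of
replicates); spatial-effect detection uses 20 replicates of 200
counties with field sd 0.8; oracle-equivalence checks run at
n ≤ 150 where exact or brute-force references are computable. The
acceptance script reports one pipeline run (240 counties, 30%
registry coverage) and one 400-county recovery fit.

# Known limitations

* The Laplace approximation underestimates skewness of strongly
  non-Gaussian marginals (very low counts); the grid mixture mitigates
  but does not remove this.
* Coarse meshes inflate the field's marginal variance (see above);
  `max_edge` should be at most about a third of the expected range.
* The migration adjustment operates at province × stratum level, as
  the stock data dictate; county-level resident rates inherit the
  province-stratum case ratio.
* Indirect standardization assumes the standard schedule's age shape
  holds within provinces up to a level shift; strong province-specific
  age effects would bias ASIR.
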