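Package: mobidence
Title: Migration-Adjusted Small-Area Disease Incidence Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian geostatistical estimation of small-area disease
    incidence from partial registry coverage, with adjustment of incident
    cases for internal migration between household-registered and resident
    populations. Implements a Matern SPDE Gaussian Markov random field
    Poisson model fitted by Laplace approximation over a hyperparameter
    grid, covariate screening (AIC ranking, pairwise-correlation and VIF
    filters), migrant-weighted reallocation of cases between provinces,
    indirect age standardization against a standard population, and
    global/local Moran spatial-autocorrelation cluster detection. Includes
    a synthetic-data generator that emulates the statistical structure of
    county-level cancer-registry data in a household-registration system.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
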