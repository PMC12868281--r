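# Shared fixtures and independent oracles for the test suite.

# Simulate a complete county dataset under the standard study conditions.
sim_dataset <- function(seed, n_provinces = 4, counties_per_province = 100,
                        urban_fraction = 0.4, base_pop = 250000,
                        migrant_rate = 0.1, young_skew = 4,
                        n_covariates = 3, n_collinear_pairs = 0,
                        spatial_corr = 0, beta = c("(Intercept)" = 0,
                                                   cov1 = 0.3),
                        spatial_range = 3, spatial_sd = 0.4,
                        registry_fraction = 1) {
  geo <- generate_geography(n_provinces, counties_per_province,
                            urban_fraction, seed = seed)
  geo <- simulate_populations_and_migration(
    geo, base_pop = base_pop, migrant_rate = migrant_rate,
    young_skew = young_skew, seed = seed + 1000)
  geo <- simulate_covariates(geo, n_covariates, n_collinear_pairs,
                             spatial_corr, seed = seed + 2000)
  truth <- make_ground_truth(geo, beta = beta, spatial_range = spatial_range,
                             spatial_sd = spatial_sd, seed = seed + 3000)
  sim <- simulate_registry_cases(geo, truth, registry_fraction,
                                 seed = seed + 4000)
  sim$truth <- truth
  sim
}

fit_dataset <- function(sim, covariates = c("cov1", "cov2", "cov3"),
                        max_edge = 2, boundary_extension = 3,
                        grid_n = 5, ...) {
  co <- sim$counties
  mesh <- build_mesh(cbind(co$x, co$y), max_edge = max_edge,
                     boundary_extension = boundary_extension)
  fit <- spde_fit(co$observed_cases, co$expected_hrp,
                  X = as.matrix(co[, covariates, drop = FALSE]), mesh = mesh,
                  range_grid = exp(seq(log(1), log(10), length.out = grid_n)),
                  sill_grid = exp(seq(log(0.01), log(5),
                                      length.out = grid_n)),
                  ...)
  list(fit = fit, mesh = mesh, counties = co)
}

# dense weight matrix of a spatial_weights object
dense_weights <- function(w) {
  n <- length(w$ids)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- w$neighbors[[i]]
    if (length(nb)) W[i, nb] <- w$weights[[i]]
  }
  W
}

# brute-force Moran's I: explicit double sum over a dense weight matrix
moran_brute <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  s0 <- sum(W)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- acc + W[i, j] * z[i] * z[j]
  }
  (n / s0) * acc / sum(z^2)
}

# brute-force local Moran statistics
local_moran_brute <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  vapply(seq_len(n), function(i) z[i] * sum(W[i, ] * z) / m2, numeric(1))
}

# adjacency data frame for a rectangular grid (rook or queen)
grid_adjacency <- function(nrow, ncol, queen = TRUE,
                           ids = NULL) {
  if (is.null(ids)) ids <- sprintf("g%03d", seq_len(nrow * ncol))
  cell <- function(r, c) (r - 1) * ncol + c
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow)) for (c in seq_len(ncol)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (!queen && abs(dr) + abs(dc) != 1) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nrow && c2 >= 1 && c2 <= ncol) {
        from <- c(from, cell(r, c)); to <- c(to, cell(r2, c2))
      }
    }
  }
  data.frame(county_id = ids[from], neighbor_id = ids[to],
             stringsAsFactors = FALSE)
}

# independent ridge-penalized Poisson IRLS solver (oracle for the
# non-spatial posterior mode)
irls_poisson_ridge <- function(y, offset, X1, prior_prec,
                               tol = 1e-12, max_iter = 200) {
  beta <- rep(0, ncol(X1))
  for (it in seq_len(max_iter)) {
    eta <- offset + X1 %*% beta
    mu <- exp(eta)
    Wd <- as.numeric(mu)
    zwork <- eta - offset + (y - mu) / mu
    M <- t(X1) %*% (Wd * X1) + prior_prec
    b <- t(X1) %*% (Wd * zwork)
    beta_new <- solve(M, b)
    if (max(abs(beta_new - beta)) < tol) return(as.numeric(beta_new))
    beta <- beta_new
  }
  as.numeric(beta)
}

read_stamped_csv_for_test <- function(path) {
  read.csv(path, comment.char = "#", check.names = FALSE,
           stringsAsFactors = FALSE)
}
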