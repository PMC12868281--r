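test_that("geography respects requested counts, strata and determinism", {
  geo <- generate_geography(4, 25, 0.4, seed = 1)
  expect_equal(nrow(geo$counties), 100)
  expect_equal(length(unique(geo$counties$province_id)), 4)
  expect_equal(sum(geo$counties$stratum == "urban"), 40)
  expect_false(any(duplicated(geo$counties$county_id)))
  # jitter stays below 0.3 grid units
  expect_true(all(abs(geo$counties$x - geo$counties$col) < 0.3))
  expect_true(all(abs(geo$counties$y - geo$counties$row) < 0.3))

  # degenerate two-county map: a single adjacency edge (both directions)
  tiny <- generate_geography(2, 1, 0, seed = 7)
  expect_equal(nrow(tiny$counties), 2)
  expect_equal(sum(tiny$counties$stratum == "urban"), 0)
  expect_equal(nrow(tiny$adjacency), 2)

  # identical seeds reproduce identical objects
  expect_identical(generate_geography(3, 9, 0.5, seed = 3),
                   generate_geography(3, 9, 0.5, seed = 3))

  expect_error(generate_geography(1, 10, 0.5, seed = 1), "n_provinces")
  expect_error(generate_geography(4, 10, 1.4, seed = 1), "urban_fraction")
})

test_that("populations and migration conserve national person-years", {
  for (s in c(2, 11, 29)) {
    geo <- generate_geography(4, 25, 0.4, seed = s)
    geo <- simulate_populations_and_migration(geo, migrant_rate = 0.25,
                                              young_skew = 4, seed = s)
    bands <- mobidence:::county_age_bands(geo$counties)
    hrp <- as.matrix(geo$counties[, mobidence:::hrp_cols(bands)])
    rp <- as.matrix(geo$counties[, mobidence:::rp_cols(bands)])
    expect_identical(sum(hrp), sum(rp))
    expect_true(all(rp >= 0))
    # province x band consistency with the flow table
    net <- rowsum(rp - hrp, geo$counties$province_id)
    flows <- geo$migration
    for (p in rownames(net)) {
      inflow <- sum(flows$count[flows$dest_province == p])
      outflow <- sum(flows$count[flows$origin_province == p])
      expect_equal(as.numeric(sum(net[p, ])), as.numeric(inflow - outflow))
    }
    expect_true(all(flows$origin_province != flows$dest_province))
  }
})

test_that("zero migration is the identity and skew concentrates working ages", {
  geo <- generate_geography(4, 25, 0.4, seed = 5)
  none <- simulate_populations_and_migration(geo, migrant_rate = 0, seed = 5)
  bands <- mobidence:::county_age_bands(none$counties)
  expect_identical(unname(as.matrix(none$counties[, mobidence:::hrp_cols(bands)])),
                   unname(as.matrix(none$counties[, mobidence:::rp_cols(bands)])))
  expect_equal(nrow(none$migration), 0)

  mig <- simulate_populations_and_migration(geo, migrant_rate = 0.25,
                                            young_skew = 4, seed = 2)
  bands <- mobidence:::county_age_bands(mig$counties)
  mid <- mobidence:::age_band_midpoints(bands)
  working <- bands[mid >= 20 & mid < 50]
  mig_share <- sum(mig$migration$count[mig$migration$age_band %in% working]) /
    sum(mig$migration$count)
  hrp <- colSums(mig$counties[, mobidence:::hrp_cols(bands)])
  hrp_share <- sum(hrp[bands %in% working]) / sum(hrp)
  expect_gt(mig_share, hrp_share)
})

test_that("covariates are standardized with requested collinearity", {
  geo <- generate_geography(4, 25, 0.4, seed = 5)
  one <- simulate_covariates(geo, 1, 0, 0, seed = 5)
  expect_lt(abs(sd(one$counties$cov1) - 1), 1e-6)
  expect_lt(abs(mean(one$counties$cov1)), 1e-12)

  six <- simulate_covariates(geo, 6, 1, 0, seed = 5)
  X <- as.matrix(six$counties[, paste0("cov", 1:6)])
  R <- abs(cor(X)); diag(R) <- 0
  high <- which(R > 0.8, arr.ind = TRUE)
  # exactly the constructed pair (cov1, cov2) exceeds 0.8
  expect_equal(nrow(high), 2)
  expect_setequal(as.vector(high), c(1, 2))
  expect_gt(R[1, 2], 0.95)

  smooth <- simulate_covariates(geo, 3, 0, 0.9, seed = 5)
  w <- build_weights(smooth$adjacency, ids = smooth$counties$county_id)
  for (j in 1:3) {
    mi <- morans_i(smooth$counties[[paste0("cov", j)]], w,
                   permutations = 99, seed = 1)
    expect_gt(mi$I, 0)
  }

  expect_error(simulate_covariates(geo, 3, 2, 0, seed = 1), "pairs")
})

test_that("registry counts are Poisson with the intended mean structure", {
  geo <- generate_geography(3, 10, 0.4, seed = 8)
  geo <- simulate_populations_and_migration(geo, migrant_rate = 0, seed = 8)
  geo <- simulate_covariates(geo, 1, 0, 0, seed = 8)
  truth <- make_ground_truth(geo, beta = c("(Intercept)" = 0),
                             spatial_range = 3, spatial_sd = 0, seed = 8)

  full <- simulate_registry_cases(geo, truth, 1, seed = 1)
  expect_true(all(full$counties$is_registry))
  expect_false(any(is.na(full$counties$observed_cases)))

  part <- simulate_registry_cases(geo, truth, 0.5, seed = 1)
  expect_identical(is.na(part$counties$observed_cases),
                   !part$counties$is_registry)
  # registry selection is stratified by urban/rural
  for (s in c("urban", "rural")) {
    idx <- part$counties$stratum == s
    expect_equal(sum(part$counties$is_registry[idx]), round(0.5 * sum(idx)))
  }

  # a county with zero population never produces cases
  geo0 <- geo
  bands <- mobidence:::county_age_bands(geo0$counties)
  geo0$counties[1, c(mobidence:::hrp_cols(bands),
                     mobidence:::rp_cols(bands))] <- 0L
  truth0 <- make_ground_truth(geo0, beta = c("(Intercept)" = 0),
                              spatial_range = 3, spatial_sd = 0, seed = 8)
  for (s in 1:5) {
    z <- simulate_registry_cases(geo0, truth0, 1, seed = s)
    expect_identical(z$counties$observed_cases[1], 0L)
  }

  # with no covariate effect and no field, mean(cases / E) -> 1
  E <- full$counties$expected_hrp
  ratios <- vapply(1:1000, function(s) {
    z <- simulate_registry_cases(geo, truth, 1, seed = s)
    mean(z$counties$observed_cases / E)
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1), 3 * se + 1e-3)
})

test_that("sampled latent field matches the requested marginal variance", {
  geo <- generate_geography(4, 25, 0.4, seed = 3)
  co <- geo$counties
  mesh <- build_mesh(cbind(co$x, co$y), max_edge = 0.8,
                     boundary_extension = 4)
  expect_gt(mesh$n_vertices, 200)
  sigma <- 0.7
  Q <- spde_precision(mesh, spde_hyper(3, sigma))
  set.seed(42)
  u <- sample_gmrf(Q, 500)
  at_counties <- as.matrix(mesh$A %*% u)
  expect_lt(abs(mean(at_counties^2) / sigma^2 - 1), 0.15)
})
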