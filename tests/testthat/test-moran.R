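test_that("weights construction follows queen contiguity rules", {
  adj <- grid_adjacency(2, 2, queen = TRUE)
  w <- build_weights(adj)
  expect_equal(lengths(w$neighbors), rep(3L, 4))
  expect_true(all(unlist(w$weights) == 1 / 3))

  path <- data.frame(county_id = c("a", "b", "b", "c", "c", "d"),
                     neighbor_id = c("b", "a", "c", "b", "d", "c"))
  wp <- build_weights(path)
  expect_equal(lengths(wp$neighbors), c(1L, 2L, 2L, 1L))

  lone <- build_weights(path, ids = c("a", "b", "c", "d", "island"))
  expect_equal(lone$isolates, "island")

  asym <- data.frame(county_id = "a", neighbor_id = "b")
  expect_error(build_weights(asym), "symmetric")
  selfn <- data.frame(county_id = c("a", "a"), neighbor_id = c("a", "a"))
  expect_error(build_weights(selfn), "self")
})

test_that("Moran's I matches hand-computed micro examples", {
  path <- data.frame(county_id = c("a", "b", "b", "c", "c", "d"),
                     neighbor_id = c("b", "a", "c", "b", "d", "c"))
  w <- build_weights(path)
  res <- morans_i(c(1, 1, 0, 0), w, permutations = 99, seed = 1)
  expect_equal(res$I, 0.5, tolerance = 1e-12)

  rook <- grid_adjacency(2, 2, queen = FALSE)
  w2 <- build_weights(rook)
  res2 <- morans_i(c(1, 0, 0, 1), w2, permutations = 99, seed = 1)
  expect_equal(res2$I, -1, tolerance = 1e-12)

  expect_error(morans_i(rep(2, 4), w2), "variance")
})

test_that("Moran's I equals a dense brute-force double sum", {
  for (s in 1:5) {
    set.seed(s)
    nr <- sample(4:6, 1); nc <- sample(4:7, 1)
    adj <- grid_adjacency(nr, nc)
    w <- build_weights(adj)
    x <- rnorm(nr * nc)
    expect_equal(morans_i(x, w, permutations = 9, seed = 1)$I,
                 moran_brute(x, dense_weights(w)), tolerance = 1e-10)
  }
})

test_that("local statistics sum to n times the global statistic", {
  for (s in 1:3) {
    set.seed(s)
    adj <- grid_adjacency(5, 6)
    w <- build_weights(adj)
    x <- rnorm(30)
    res <- lisa_clusters(x, w, permutations = 49, seed = s)
    expect_equal(sum(res$local$local_i), 30 * res$global_I,
                 tolerance = 1e-8)
    expect_equal(res$local$local_i, local_moran_brute(x, dense_weights(w)),
                 tolerance = 1e-10)
  }
})

test_that("permutation null of Moran's I is centered at -1/(n-1)", {
  set.seed(11)
  adj <- grid_adjacency(5, 5)
  w <- build_weights(adj)
  W <- dense_weights(w)
  x <- as.numeric(outer(1:5, 1:5, "+"))  # strongly clustered surface
  perms <- replicate(3000, moran_brute(sample(x), W))
  se <- sd(perms) / sqrt(length(perms))
  expect_lt(abs(mean(perms) - (-1 / 24)), 4 * se)
})

test_that("a clustered latent surface is detected as autocorrelated", {
  hits <- vapply(1:5, function(s) {
    sim <- sim_dataset(700 + s, spatial_sd = 0.8)
    co <- sim$counties
    w <- build_weights(sim$adjacency, ids = co$county_id)
    rate <- co$observed_cases / co$expected_hrp
    res <- morans_i(rate, w, permutations = 999, seed = s)
    res$I > 0 && res$p_value <= 0.001
  }, logical(1))
  expect_equal(sum(hits), 5)
})

test_that("LISA labels a hot block HH with an LH cold ring", {
  adj <- grid_adjacency(10, 10)
  w <- build_weights(adj)
  x <- rep(0, 100)
  hot <- c(34:36, 44:46, 54:56)        # rows 4-6, cols 4-6
  x[hot] <- 10
  res <- lisa_clusters(x, w, permutations = 199, seed = 3)
  center <- 45                          # interior of the hot block
  expect_equal(res$local$quadrant[center], "HH")
  expect_true(res$local$significant[center])
  ring <- c(33, 43, 53, 63, 23:27)      # cold cells touching the block
  expect_true(all(res$local$quadrant[ring] == "LH"))

  # quadrants and significance invariant under affine rescaling
  res2 <- lisa_clusters(2 * x + 5, w, permutations = 199, seed = 3)
  expect_identical(res$local$quadrant, res2$local$quadrant)
  expect_identical(res$local$significant, res2$local$significant)
  # identical seed reproduces identical flags
  res3 <- lisa_clusters(x, w, permutations = 199, seed = 3)
  expect_identical(res$local, res3$local)
})

test_that("excess risk is the observed-to-expected ratio", {
  expect_equal(excess_risk(c(2, 4), c(2, 2)), c(1, 2))
  expect_true(is.na(excess_risk(1, 0)))
  expect_error(excess_risk(-1, 2), "nonnegative")
  # counties with a high latent field show elevated excess risk
  sim <- sim_dataset(711, spatial_sd = 0.8)
  er <- excess_risk(sim$counties$observed_cases, sim$counties$expected_hrp)
  top <- sim$truth$field_values >= quantile(sim$truth$field_values, 0.9)
  expect_gt(mean(er[top]), 1)
})

test_that("cluster summaries count significant counties and population", {
  sim <- sim_dataset(721, n_provinces = 2, counties_per_province = 9,
                     migrant_rate = 0)
  co <- sim$counties
  fake <- list(local = data.frame(
    id = co$county_id,
    local_i = 1,
    quadrant = ifelse(co$province_id == "p01", "HH", "LL"),
    p_value = ifelse(co$province_id == "p01", 0.01, 0.5),
    significant = co$province_id == "p01",
    stringsAsFactors = FALSE))
  summ <- cluster_summary(fake, co)
  p1 <- summ[summ$province == "p01", ]
  expect_equal(p1$pct_counties_high, 100)
  expect_equal(p1$pct_population_high, 100)
  expect_equal(p1$pct_counties_low, 0)
  p2 <- summ[summ$province == "p02", ]
  expect_equal(p2$pct_counties_high, 0)
  expect_equal(p2$pct_population_low, 0)  # LL quadrant but not significant
  expect_error(cluster_summary(fake, co[-1, ]), "match")
})
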