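test_that("AIC ranking identifies the true risk driver", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 300
    X <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("cov", 1:4)))
    E <- runif(n, 20, 60)
    y <- rpois(n, E * exp(0.5 * X[, 2]))
    ranked <- aic_rank(y, E, as.data.frame(X))
    ranked$covariate[1] == "cov2"
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("AIC algebra: useless covariates and duplicates behave", {
  set.seed(1)
  n <- 150
  E <- runif(n, 20, 60)
  y <- rpois(n, E)
  noise <- rnorm(n)
  covs <- data.frame(a = noise, b = noise, flat = rep(1, n))
  ranked <- aic_rank(y, E, covs)
  # a duplicated column gets an identical AIC
  expect_lt(abs(ranked$aic[ranked$covariate == "a"] -
                  ranked$aic[ranked$covariate == "b"]), 1e-6)
  # an uninformative covariate can cost at most its 2-unit AIC penalty
  null_aic <- AIC(glm(y ~ 1 + offset(log(E)), family = poisson()))
  expect_lte(ranked$aic[ranked$covariate == "a"], null_aic + 2 + 1e-8)
  # constant covariate: flagged, carries the intercept-only AIC
  flat <- ranked[ranked$covariate == "flat", ]
  expect_true(flat$constant)
  expect_equal(flat$aic, null_aic)
})

test_that("correlation filter drops duplicates and follows the greedy pass", {
  set.seed(2)
  n <- 400
  # columns exactly orthonormal and orthogonal to the intercept
  z <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, -1]
  x1 <- z[, 1]
  covs <- data.frame(x1 = x1, x2 = x1, x3 = z[, 2])
  res <- correlation_filter(covs, threshold = 0.8)
  expect_equal(res$retained, c("x1", "x3"))
  expect_equal(res$dropped$covariate, "x2")
  expect_equal(res$dropped$r, 1.0)

  # orthogonal pair: both retained
  res2 <- correlation_filter(data.frame(a = z[, 1], b = z[, 2]), 0.8)
  expect_equal(res2$retained, c("a", "b"))

  # r = (0.85, 0.3, 0.3): only the later member of the 0.85 pair drops
  a <- z[, 1]
  b <- 0.85 * z[, 1] + sqrt(1 - 0.85^2) * z[, 2]
  c3 <- 0.3 * z[, 1] + sqrt(1 - 0.3^2) * z[, 3]
  res3 <- correlation_filter(data.frame(a = a, b = b, c3 = c3), 0.8)
  expect_equal(res3$retained, c("a", "c3"))
  expect_equal(res3$dropped$covariate, "b")
  expect_equal(res3$dropped$partner, "a")
  expect_lt(abs(res3$dropped$r - 0.85), 1e-9)

  # zero-variance columns are flagged separately
  res4 <- correlation_filter(data.frame(a = a, z = rep(2, n)), 0.8)
  expect_equal(res4$zero_variance, "z")
})

test_that("VIF filter matches closed forms and removes collinear sets", {
  set.seed(3)
  n <- 200
  z <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, -1]
  orth <- data.frame(a = z[, 1], b = z[, 2], c = z[, 3])
  res <- vif_filter(orth, threshold = 10)
  expect_equal(res$retained, c("a", "b", "c"))
  expect_equal(unname(mobidence:::vif_values(as.matrix(orth))),
               rep(1, 3), tolerance = 1e-9)

  # pairwise r = 0.5 gives VIF = 1/(1 - 0.25) = 4/3 and both survive
  pair <- data.frame(a = z[, 1], b = 0.5 * z[, 1] + sqrt(0.75) * z[, 2])
  v <- mobidence:::vif_values(as.matrix(pair))
  expect_equal(unname(v), c(4 / 3, 4 / 3), tolerance = 1e-9)
  expect_equal(vif_filter(pair)$retained, c("a", "b"))

  # x3 = x1 + x2 + small noise: exactly one member removed, VIF > 10
  x1 <- z[, 1]; x2 <- z[, 2]
  x3 <- x1 + x2 + rnorm(n, 0, 0.01)
  res3 <- vif_filter(data.frame(x1 = x1, x2 = x2, x3 = x3), threshold = 10)
  expect_equal(length(res3$retained), 2)
  expect_equal(nrow(res3$dropped), 1)
  expect_gt(res3$dropped$vif, 10)

  # perfect collinearity is reported as infinite
  dup <- data.frame(a = x1, b = x1, c = z[, 3])
  v <- suppressWarnings(mobidence:::vif_values(as.matrix(dup)))
  expect_true(any(is.infinite(v)))
})

test_that("the full screening funnel retains the true driver", {
  keep <- vapply(1:10, function(s) {
    sim <- sim_dataset(s + 100, counties_per_province = 50,
                       n_covariates = 6, n_collinear_pairs = 1,
                       beta = c("(Intercept)" = 0, cov3 = 0.5),
                       spatial_sd = 0.2)
    co <- sim$counties
    rep <- screen_covariates(co$observed_cases, co$expected_hrp,
                             co[, paste0("cov", 1:6)])
    # each input covariate lands in exactly one disposition
    dispo <- c(rep$retained, rep$dropped_correlation$covariate,
               rep$dropped_vif$covariate, rep$zero_variance)
    expect_setequal(dispo, paste0("cov", 1:6))
    expect_false(any(duplicated(dispo)))
    "cov3" %in% rep$retained
  }, logical(1))
  expect_gte(sum(keep), 9)
})

test_that("screening is stable under column permutation", {
  sim <- sim_dataset(42, counties_per_province = 50, n_covariates = 5,
                     beta = c("(Intercept)" = 0, cov2 = 0.4),
                     spatial_sd = 0.2)
  co <- sim$counties
  covs <- co[, paste0("cov", 1:5)]
  r1 <- screen_covariates(co$observed_cases, co$expected_hrp, covs)
  r2 <- screen_covariates(co$observed_cases, co$expected_hrp,
                          covs[, c(4, 2, 5, 1, 3)])
  expect_setequal(r1$retained, r2$retained)
})
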