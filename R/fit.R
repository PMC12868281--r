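#' Penalized-complexity-style hyperparameter priors
#'
#' Exponential shrinkage priors on the Matern hyperparameters:
#' `P(range < range0) = 0.5` and `P(sigma > sigma_u) = alpha_sigma`,
#' plus independent zero-mean Gaussian priors with sd `beta_sd` on the
#' fixed effects (intercept included).
#'
#' @param range0 prior median of the spatial range.
#' @param sigma_u,alpha_sigma tail definition for the field sd.
#' @param beta_sd prior sd of fixed effects.
#' @return list of class `spde_priors`.
#' @export
spde_priors <- function(range0 = 3, sigma_u = 1, alpha_sigma = 0.1,
                        beta_sd = 10) {
  structure(list(range0 = range0, sigma_u = sigma_u,
                 alpha_sigma = alpha_sigma, beta_sd = beta_sd,
                 lambda_range = log(2) * range0,
                 lambda_sigma = -log(alpha_sigma) / sigma_u),
            class = "spde_priors")
}

log_hyper_prior <- function(range, sigma, priors) {
  lr <- priors$lambda_range; ls <- priors$lambda_sigma
  # PC prior on range (2D): pi(rho) = lr * rho^-2 * exp(-lr / rho)
  log(lr) - 2 * log(range) - lr / range + log(ls) - ls * sigma
}

default_range_grid <- function(k = 7) exp(seq(log(1), log(10), length.out = k))
default_sill_grid <- function(k = 7) exp(seq(log(0.01), log(5), length.out = k))

# log-grid integration measure: Jacobian rho*sigma times the log-spacing cell
log_grid_measure <- function(range_grid, sigma_grid) {
  gap <- function(g) {
    lg <- log(g)
    if (length(lg) == 1L) return(1)
    d <- diff(lg)
    (c(d[1], d) + c(d, d[length(d)])) / 2
  }
  list(range = gap(range_grid), sigma = gap(sigma_grid))
}

chm_logdet <- function(ch) {
  # log-determinant of the matrix factored by a CHMfactor
  2 * Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus
}

# Newton optimization of the latent-Gaussian posterior mode.
# loglik and derivatives depend on the family:
#   poisson:  y ~ Pois(exp(off + B z))
#   gaussian: y ~ N(off + B z, noise_sd^2), identity link
newton_mode <- function(y, off, B, Pmat, family = "poisson", noise_sd = 1,
                        z0 = NULL, max_iter = 100, tol = 1e-6) {
  d <- ncol(B)
  z <- if (is.null(z0)) numeric(d) else z0
  obj_fun <- function(z, eta) {
    if (family == "poisson") {
      if (any(eta > 60)) return(-Inf)
      sum(y * eta - exp(eta)) - 0.5 * sum(z * as.numeric(Pmat %*% z))
    } else {
      -0.5 * sum((y - eta)^2) / noise_sd^2 -
        0.5 * sum(z * as.numeric(Pmat %*% z))
    }
  }
  trace <- numeric(0)
  eta <- off + as.numeric(B %*% z)
  obj <- obj_fun(z, eta)
  converged <- FALSE
  iter <- 0
  H <- NULL
  while (iter < max_iter) {
    iter <- iter + 1
    if (family == "poisson") {
      mu <- exp(pmin(eta, 60))
      grad <- as.numeric(Matrix::t(B) %*% (y - mu)) - as.numeric(Pmat %*% z)
      W <- mu
    } else {
      grad <- as.numeric(Matrix::t(B) %*% (y - eta)) / noise_sd^2 -
        as.numeric(Pmat %*% z)
      W <- rep(1 / noise_sd^2, length(y))
    }
    gnorm <- max(abs(grad))
    trace <- c(trace, gnorm)
    if (gnorm < tol) { converged <- TRUE; break }
    H <- forceSymmetric(Matrix::t(B) %*% (W * B) + Pmat)
    ch <- Cholesky(H, LDL = FALSE, perm = TRUE)
    step <- as.numeric(solve(ch, grad))
    # backtracking line search
    alpha <- 1
    repeat {
      z_new <- z + alpha * step
      eta_new <- off + as.numeric(B %*% z_new)
      obj_new <- obj_fun(z_new, eta_new)
      if (is.finite(obj_new) && obj_new >= obj - 1e-9 * (1 + abs(obj))) break
      alpha <- alpha / 2
      if (alpha < 1e-10) break
    }
    if (alpha < 1e-10) { converged <- gnorm < 1e-4; break }
    z <- z_new; eta <- eta_new; obj <- obj_new
  }
  if (!converged) {
    cond <- simpleError(sprintf(
      "Newton optimization did not converge after %d iterations (last gradient norms: %s)",
      iter, paste(signif(utils::tail(trace, 5), 3), collapse = ", ")))
    cond$trace <- trace
    stop(cond)
  }
  if (family == "poisson") {
    W <- exp(pmin(eta, 60))
  } else {
    W <- rep(1 / noise_sd^2, length(y))
  }
  H <- forceSymmetric(Matrix::t(B) %*% (W * B) + Pmat)
  ch <- Cholesky(H, LDL = FALSE, perm = TRUE)
  ll <- if (family == "poisson") {
    sum(dpois(y, exp(pmin(eta, 60)), log = TRUE))
  } else {
    sum(dnorm(y, eta, noise_sd, log = TRUE))
  }
  list(mode = z, eta = eta, H = H, chol = ch, loglik = ll,
       iterations = iter, trace = trace)
}

#' Fit the Bayesian spatial Poisson incidence model
#'
#' Latent-Gaussian Poisson regression with a log offset, fixed effects
#' under weak Gaussian priors, and (optionally) a Matern SPDE spatial
#' field. Inference follows the nested-Laplace recipe: for every point of
#' a (range x sill) hyperparameter grid, the joint mode of
#' `(beta, field)` is found by Newton iteration, a Gaussian (Laplace)
#' approximation is formed at the mode, grid weights are proportional to
#' the hyper prior times the Laplace-approximated marginal likelihood, and
#' posterior marginals are grid mixtures of Gaussians. Counties with `NA`
#' cases (non-registry) are excluded from the likelihood but receive
#' fitted rates.
#'
#' @param cases observed counts; `NA` marks counties outside the registry.
#' @param expected offset expected counts (> 0 wherever cases observed).
#' @param X covariate matrix (columns standardized; no intercept column —
#'   an intercept is added internally), or `NULL`.
#' @param mesh a [build_mesh()] over all county centroids; required when
#'   `spatial = TRUE`.
#' @param spatial include the SPDE field?
#' @param range_grid,sill_grid hyperparameter grid; `sill_grid` is the
#'   partial sill, interpreted as the field variance when
#'   `sill_is_variance` is `TRUE` (default), else as the sd.
#' @param sill_is_variance see above.
#' @param priors a [spde_priors()].
#' @param population optional county male populations; when supplied,
#'   fitted rates per 100,000 are reported.
#' @param family `"poisson"` (the model) or `"gaussian"` (identity-link,
#'   known `noise_sd`; used for exactness checks against conjugate
#'   posteriors).
#' @param noise_sd Gaussian-family noise sd.
#' @param max_iter,tol Newton controls (gradient infinity-norm).
#' @return object of class `spde_fit`; see Details.
#' @details The returned object contains `grid` (hyper points with
#'   normalized weights), `beta` (mixture mean, sd and 2.5/97.5
#'   percentiles per fixed effect), `linpred` (the same for every county
#'   log relative risk), `rates` (per 100,000, when `population` given),
#'   `mll` (log marginal likelihood), and the per-grid-point modes and
#'   Cholesky factors needed by [model_criteria()] and
#'   [validate_coverage()].
#' @export
spde_fit <- function(cases, expected, X = NULL, mesh = NULL,
                     spatial = TRUE,
                     range_grid = default_range_grid(),
                     sill_grid = default_sill_grid(),
                     sill_is_variance = TRUE,
                     priors = spde_priors(),
                     population = NULL,
                     family = c("poisson", "gaussian"),
                     noise_sd = 1,
                     max_iter = 100, tol = 1e-6) {
  family <- match.arg(family)
  n <- length(cases)
  if (length(expected) != n) stop("`expected` length mismatch", call. = FALSE)
  obs <- if (family == "poisson") {
    which(!is.na(cases) & expected > 0)
  } else {
    which(!is.na(cases))
  }
  if (!length(obs)) stop("no usable observations", call. = FALSE)
  y <- cases[obs]
  off <- if (family == "poisson") log(expected[obs]) else expected[obs]
  off_all <- if (family == "poisson") log(pmax(expected, 1e-300)) else expected

  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("`X` rows must match counties", call. = FALSE)
    if (any(!is.finite(X))) stop("`X` must be finite", call. = FALSE)
  }
  X1 <- if (is.null(X)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cbind(`(Intercept)` = 1, X)
  }
  p <- ncol(X1)
  beta_prec <- Diagonal(p, 1 / priors$beta_sd^2)

  if (spatial) {
    if (is.null(mesh)) stop("`mesh` required for a spatial fit", call. = FALSE)
    if (!all(is.finite(range_grid)) || !all(is.finite(sill_grid)) ||
        any(range_grid <= 0) || any(sill_grid <= 0)) {
      stop("hyperparameter grids must be positive and finite", call. = FALSE)
    }
    sigma_grid <- if (sill_is_variance) sqrt(sill_grid) else sill_grid
    grid <- expand.grid(range = range_grid, sigma = sigma_grid,
                        KEEP.OUT.ATTRS = FALSE)
    meas <- log_grid_measure(range_grid, sigma_grid)
    grid$log_measure <- log(meas$range[match(grid$range, range_grid)]) +
      log(meas$sigma[match(grid$sigma, sigma_grid)]) +
      log(grid$range) + log(grid$sigma)
    A_obs <- mesh$A[obs, , drop = FALSE]
    B <- cbind(as(X1[obs, , drop = FALSE], "CsparseMatrix"), A_obs)
    Bfull <- cbind(as(X1, "CsparseMatrix"), mesh$A)
  } else {
    grid <- data.frame(range = NA_real_, sigma = NA_real_, log_measure = 0)
    B <- as(X1[obs, , drop = FALSE], "CsparseMatrix")
    Bfull <- as(X1, "CsparseMatrix")
  }
  d <- ncol(B)

  K <- nrow(grid)
  logw <- numeric(K)
  modes <- vector("list", K)
  chols <- vector("list", K)
  beta_m <- matrix(0, K, p); beta_s <- matrix(0, K, p)
  eta_m <- matrix(0, K, n); eta_s <- matrix(0, K, n)
  iters <- integer(K)
  z0 <- NULL
  for (k in seq_len(K)) {
    if (spatial) {
      Q <- spde_precision(mesh, spde_hyper(grid$range[k], grid$sigma[k]))
      Pmat <- bdiag(beta_prec, Q)
      ldP <- p * log(1 / priors$beta_sd^2) +
        chm_logdet(Cholesky(forceSymmetric(Q), LDL = FALSE, perm = TRUE))
    } else {
      Pmat <- beta_prec
      ldP <- p * log(1 / priors$beta_sd^2)
    }
    opt <- newton_mode(y, off, B, Pmat, family = family, noise_sd = noise_sd,
                       z0 = z0, max_iter = max_iter, tol = tol)
    z0 <- opt$mode
    modes[[k]] <- opt$mode
    chols[[k]] <- opt$chol
    iters[k] <- opt$iterations
    quad <- 0.5 * sum(opt$mode * as.numeric(Pmat %*% opt$mode))
    laplace <- opt$loglik - quad + 0.5 * ldP - 0.5 * chm_logdet(opt$chol)
    lp <- if (spatial) {
      log_hyper_prior(grid$range[k], grid$sigma[k], priors)
    } else 0
    logw[k] <- laplace + lp + grid$log_measure[k]

    # conditional marginal sds: diag of H^-1 for beta, b' H^-1 b for linpreds
    rhs <- Matrix::t(Bfull)
    V <- solve(opt$chol, rhs)
    eta_var <- Matrix::colSums(rhs * V)
    Ei <- sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                       dims = c(d, p))
    Vb <- solve(opt$chol, Ei)
    beta_var <- Matrix::colSums(Ei * Vb)
    beta_m[k, ] <- opt$mode[seq_len(p)]
    beta_s[k, ] <- sqrt(pmax(beta_var, 0))
    eta_m[k, ] <- off_all * 0 + as.numeric(Bfull %*% opt$mode)
    eta_s[k, ] <- sqrt(pmax(eta_var, 0))
  }

  mll <- logsumexp(logw)
  w <- exp(logw - mll)
  w <- w / sum(w)
  grid$logw <- logw
  grid$weight <- w

  mix_stats <- function(m, s) {
    mean <- colSums(w * m)
    second <- colSums(w * (s^2 + m^2))
    sdv <- sqrt(pmax(second - mean^2, 0))
    q <- vapply(seq_len(ncol(m)), function(j) {
      c(mixture_quantile(0.025, m[, j], s[, j], w),
        mixture_quantile(0.975, m[, j], s[, j], w))
    }, numeric(2))
    list(mean = mean, sd = sdv, q025 = q[1, ], q975 = q[2, ])
  }
  bs <- mix_stats(beta_m, beta_s)
  beta_df <- data.frame(term = colnames(X1), mean = bs$mean, sd = bs$sd,
                        q025 = bs$q025, q975 = bs$q975,
                        stringsAsFactors = FALSE)
  es <- mix_stats(eta_m, eta_s)
  linpred <- data.frame(mean = es$mean, sd = es$sd, q025 = es$q025,
                        q975 = es$q975)

  rates <- NULL
  if (!is.null(population)) {
    # posterior mean of mu = E exp(eta), lognormal component means
    mu_mean <- colSums(w * (exp(eta_m + 0.5 * eta_s^2))) * expected
    rates <- data.frame(
      fitted_cases = mu_mean,
      rate = ifelse(population > 0, mu_mean / population * 1e5, NA_real_),
      rate_q025 = ifelse(population > 0,
                         expected * exp(es$q025) / population * 1e5, NA_real_),
      rate_q975 = ifelse(population > 0,
                         expected * exp(es$q975) / population * 1e5, NA_real_)
    )
  }

  structure(list(grid = grid, beta = beta_df, linpred = linpred,
                 rates = rates, mll = mll,
                 modes = modes, chols = chols,
                 beta_m = beta_m, beta_s = beta_s,
                 eta_m = eta_m, eta_s = eta_s,
                 B_obs = B, Bfull = Bfull, y = y, obs = obs,
                 cases = cases, expected = expected,
                 off = off, off_all = off_all,
                 spatial = spatial, family = family, noise_sd = noise_sd,
                 p = p, population = population, priors = priors,
                 iterations = iters),
            class = "spde_fit")
}

#' @export
print.spde_fit <- function(x, ...) {
  cat(sprintf("spde_fit (%s%s): %d observations, %d counties, %d hyper grid points\n",
              x$family, if (x$spatial) ", spatial" else ", non-spatial",
              length(x$y), nrow(x$linpred), nrow(x$grid)))
  print(x$beta, digits = 4)
  if (x$spatial) {
    cat(sprintf("posterior mean range %.3f, field sd %.3f; MLL %.3f\n",
                hyper_posterior_mean(x)["range"],
                hyper_posterior_mean(x)["sigma"], x$mll))
  }
  invisible(x)
}

#' Posterior means of the Matern hyperparameters from the grid weights
#' @param fit an `spde_fit`.
#' @return named vector `c(range =, sigma =)`.
#' @export
hyper_posterior_mean <- function(fit) {
  if (!fit$spatial) return(c(range = NA_real_, sigma = NA_real_))
  c(range = sum(fit$grid$weight * fit$grid$range),
    sigma = sum(fit$grid$weight * fit$grid$sigma))
}

# quantile of a Gaussian mixture by CDF inversion
mixture_quantile <- function(prob, means, sds, weights) {
  keep <- weights > 1e-12
  means <- means[keep]; sds <- pmax(sds[keep], 1e-12)
  weights <- weights[keep] / sum(weights[keep])
  if (length(means) == 1L) return(qnorm(prob, means, sds))
  lo <- min(means - 10 * sds); hi <- max(means + 10 * sds)
  f <- function(x) sum(weights * pnorm((x - means) / sds)) - prob
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# draw joint latent samples from the grid-mixture Laplace approximation;
# returns list(z = d x n_draws matrix, comp = component index per draw)
sample_posterior <- function(fit, n_draws) {
  K <- nrow(fit$grid)
  comp <- sample.int(K, n_draws, replace = TRUE, prob = fit$grid$weight)
  d <- ncol(fit$B_obs)
  Z <- matrix(0, d, n_draws)
  for (k in unique(comp)) {
    idx <- which(comp == k)
    z <- matrix(rnorm(d * length(idx)), d, length(idx))
    x <- solve(fit$chols[[k]], solve(fit$chols[[k]], z, system = "Lt"),
               system = "Pt")
    Z[, idx] <- as.matrix(x) + fit$modes[[k]]
  }
  list(z = Z, comp = comp)
}

#' Model-comparison criteria from a fitted model
#'
#' Monte-Carlo DIC and WAIC from draws of the posterior mixture, plus the
#' grid-integrated log marginal likelihood (MLL). `DIC = Dbar + pD` with
#' `pD = Dbar - D(posterior mean)`; `WAIC = -2 (lppd - pWAIC)` with
#' `pWAIC` the sum of pointwise posterior log-likelihood variances.
#'
#' @param fit an `spde_fit`.
#' @param n_draws posterior draws (>= 1000 recommended).
#' @param seed integer seed for the draws.
#' @return list `dic`, `waic`, `mll`, `p_d`, `p_waic`, `warning`
#'   (non-`NULL` when `p_d < 0`, an approximation flag, not an error).
#' @export
model_criteria <- function(fit, n_draws = 1000, seed = 1) {
  stopifnot(inherits(fit, "spde_fit"))
  y <- fit$y; off <- fit$off
  ll_mat <- with_seed(seed, {
    sp <- sample_posterior(fit, n_draws)
    eta <- as.matrix(fit$B_obs %*% sp$z) + off   # n_obs x n_draws
    if (fit$family == "poisson") {
      matrix(dpois(rep(y, n_draws), as.vector(exp(pmin(eta, 60))), log = TRUE),
             length(y), n_draws)
    } else {
      matrix(dnorm(rep(y, n_draws), as.vector(eta), fit$noise_sd, log = TRUE),
             length(y), n_draws)
    }
  })
  dev <- -2 * colSums(ll_mat)
  dbar <- mean(dev)
  eta_mean <- fit$linpred$mean[fit$obs] + off
  dhat <- if (fit$family == "poisson") {
    -2 * sum(dpois(y, exp(pmin(eta_mean, 60)), log = TRUE))
  } else {
    -2 * sum(dnorm(y, eta_mean, fit$noise_sd, log = TRUE))
  }
  p_d <- dbar - dhat
  dic <- dbar + p_d
  lppd <- sum(apply(ll_mat, 1, logsumexp) - log(n_draws))
  p_waic <- sum(apply(ll_mat, 1, var))
  waic <- -2 * (lppd - p_waic)
  list(dic = dic, waic = waic, mll = fit$mll, p_d = p_d, p_waic = p_waic,
       warning = if (p_d < 0) "negative effective number of parameters (p_D)" else NULL)
}

#' Coverage of observed counts by the 95% credible intervals
#'
#' With `interval = "fitted"` (the default validation convention), each
#' observed count is checked against the closed credible interval of its
#' fitted count `E_i exp(eta_i)` — the usual BCI validation of
#' small-area disease-mapping fits. With `interval = "predictive"`,
#' Poisson observation noise is added on top of linear-predictor draws
#' by simulation; note that such in-sample posterior-predictive checks
#' are conservative (empirical coverage typically near 1).
#'
#' @param fit an `spde_fit`.
#' @param observed counts to check (default: the fitted observations).
#' @param level interval mass.
#' @param interval `"fitted"` or `"predictive"` (see above).
#' @param n_draws predictive draws (predictive intervals only).
#' @param seed integer seed (predictive intervals only).
#' @return list `coverage` (proportion in `[0, 1]`), `inside` (per-county
#'   logical), `lower`, `upper`.
#' @export
validate_coverage <- function(fit, observed = fit$y, level = 0.95,
                              interval = c("fitted", "predictive"),
                              n_draws = 1000, seed = 1) {
  stopifnot(inherits(fit, "spde_fit"))
  interval <- match.arg(interval)
  if (length(observed) != length(fit$y)) {
    stop("`observed` must match the fitted observations", call. = FALSE)
  }
  qlo <- (1 - level) / 2
  if (interval == "fitted") {
    E <- fit$expected[fit$obs]
    lo <- E * exp(vapply(fit$obs, function(i) {
      mixture_quantile(qlo, fit$eta_m[, i], fit$eta_s[, i],
                       fit$grid$weight)
    }, numeric(1)))
    hi <- E * exp(vapply(fit$obs, function(i) {
      mixture_quantile(1 - qlo, fit$eta_m[, i], fit$eta_s[, i],
                       fit$grid$weight)
    }, numeric(1)))
    lims <- cbind(lo, hi)
  } else {
    lims <- with_seed(seed, {
      sp <- sample_posterior(fit, n_draws)
      eta <- as.matrix(fit$B_obs %*% sp$z) + fit$off
      yrep <- matrix(rpois(length(eta), as.vector(exp(pmin(eta, 60)))),
                     nrow(eta), ncol(eta))
      t(apply(yrep, 1, quantile, probs = c(qlo, 1 - qlo), type = 1))
    })
  }
  inside <- observed >= lims[, 1] & observed <= lims[, 2]
  list(coverage = mean(inside), inside = inside,
       lower = lims[, 1], upper = lims[, 2])
}

#' Province-stratified k-fold cross-validation of the spatial model
#'
#' Registry counties are dealt into `k` folds within each province; the
#' model is refitted with each fold held out and held-out counties are
#' scored on the predictive log-score (log mean predictive density over
#' posterior draws) and the RMSE of predicted vs observed standardized
#' incidence ratios.
#'
#' @param cases,expected,X,mesh as in [spde_fit()].
#' @param province province id per county (stratifies the folds).
#' @param k number of folds (>= 2; `k = n` gives leave-one-out).
#' @param seed integer seed (fold assignment and criteria draws).
#' @param n_draws predictive draws per fold.
#' @param ... further arguments passed to [spde_fit()].
#' @return list `folds` (per-fold data frame: `fold`, `n_heldout`,
#'   `log_score`, `rmse_sir`), `scores` (per-heldout-county data frame),
#'   `assignment` (fold id per county, `NA` outside the registry).
#' @export
cross_validate <- function(cases, expected, X = NULL, mesh = NULL, province,
                           k = 5, seed = 1, n_draws = 500, ...) {
  n <- length(cases)
  obs <- which(!is.na(cases) & expected > 0)
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (length(obs) < k) stop("fewer registry counties than folds", call. = FALSE)
  assignment <- rep(NA_integer_, n)
  with_seed(seed, {
    counter <- 0L
    for (pv in unique(province[obs])) {
      idx <- obs[province[obs] == pv]
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- (counter + seq_along(idx) - 1L) %% k + 1L
      counter <- counter + length(idx)
    }
  })
  if (any(tabulate(assignment[obs], k) == 0L)) {
    stop("a fold received zero registry counties; lower `k`", call. = FALSE)
  }
  fold_rows <- list(); score_rows <- list()
  for (f in seq_len(k)) {
    held <- which(assignment == f)
    train_cases <- cases
    train_cases[held] <- NA
    fit <- spde_fit(train_cases, expected, X = X, mesh = mesh, ...)
    pred <- with_seed(seed + f, {
      sp <- sample_posterior(fit, n_draws)
      eta <- as.matrix(fit$Bfull[held, , drop = FALSE] %*% sp$z)
      mu <- expected[held] * exp(pmin(eta, 60))
      ll <- matrix(dpois(rep(cases[held], n_draws), as.vector(mu), log = TRUE),
                   length(held), n_draws)
      list(log_score = apply(ll, 1, logsumexp) - log(n_draws),
           sir_pred = rowMeans(exp(pmin(eta, 60))))
    })
    sir_obs <- cases[held] / expected[held]
    score_rows[[f]] <- data.frame(county = held, fold = f,
                                  log_score = pred$log_score,
                                  sir_pred = pred$sir_pred,
                                  sir_obs = sir_obs)
    fold_rows[[f]] <- data.frame(
      fold = f, n_heldout = length(held),
      log_score = mean(pred$log_score),
      rmse_sir = sqrt(mean((pred$sir_pred - sir_obs)^2)))
  }
  list(folds = do.call(rbind, fold_rows),
       scores = do.call(rbind, score_rows),
       assignment = assignment)
}

#' Sensitivity suite: spatial effect, leave-one-covariate-out, pinned grids
#'
#' Refits the model under a family of perturbed configurations and reports
#' one DIC row per configuration, all on the same data and likelihood:
#' the baseline spatial fit, the model without the spatial field,
#' each single-covariate deletion (when `loco`), and single-point
#' hyperparameter pins over `pin_ranges` x `pin_sills`.
#'
#' @param cases,expected,X,mesh,range_grid,sill_grid,... as [spde_fit()].
#' @param pin_ranges,pin_sills hyperparameter values to pin (optional).
#' @param loco refit deleting each covariate in turn?
#' @param n_draws,seed passed to [model_criteria()].
#' @return data frame `config`, `range`, `sill`, `dic`, `delta_dic`
#'   (relative to the baseline row).
#' @export
sensitivity_suite <- function(cases, expected, X = NULL, mesh = NULL,
                              range_grid = default_range_grid(),
                              sill_grid = default_sill_grid(),
                              pin_ranges = NULL, pin_sills = NULL,
                              loco = TRUE, n_draws = 1000, seed = 1, ...) {
  if (!length(range_grid) || !length(sill_grid)) {
    stop("hyperparameter grids must be non-empty", call. = FALSE)
  }
  rows <- list()
  base <- spde_fit(cases, expected, X = X, mesh = mesh, spatial = TRUE,
                   range_grid = range_grid, sill_grid = sill_grid, ...)
  base_dic <- model_criteria(base, n_draws = n_draws, seed = seed)$dic
  rows[[1]] <- data.frame(config = "baseline", range = NA_real_,
                          sill = NA_real_, dic = base_dic)
  ns <- spde_fit(cases, expected, X = X, mesh = mesh, spatial = FALSE, ...)
  rows[[2]] <- data.frame(config = "no_spatial", range = NA_real_,
                          sill = NA_real_,
                          dic = model_criteria(ns, n_draws = n_draws,
                                               seed = seed)$dic)
  if (loco && !is.null(X) && ncol(as.matrix(X)) >= 1) {
    X <- as.matrix(X)
    for (j in seq_len(ncol(X))) {
      Xj <- X[, -j, drop = FALSE]
      if (ncol(Xj) == 0L) Xj <- NULL
      fj <- spde_fit(cases, expected, X = Xj, mesh = mesh, spatial = TRUE,
                     range_grid = range_grid, sill_grid = sill_grid, ...)
      rows[[length(rows) + 1]] <- data.frame(
        config = paste0("drop_", colnames(X)[j]),
        range = NA_real_, sill = NA_real_,
        dic = model_criteria(fj, n_draws = n_draws, seed = seed)$dic)
    }
  }
  for (r in pin_ranges) for (s in pin_sills) {
    fp <- spde_fit(cases, expected, X = X, mesh = mesh, spatial = TRUE,
                   range_grid = r, sill_grid = s, ...)
    rows[[length(rows) + 1]] <- data.frame(
      config = "pinned", range = r, sill = s,
      dic = model_criteria(fp, n_draws = n_draws, seed = seed)$dic)
  }
  out <- do.call(rbind, rows)
  out$delta_dic <- out$dic - base_dic
  out
}
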