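#' Rank covariates by single-predictor Poisson AIC
#'
#' Each covariate is entered alone in a log-linear Poisson regression of
#' the registry counts with a log expected-count offset; covariates are
#' ranked by ascending AIC. A constant (zero-variance) covariate cannot
#' be fitted and receives the intercept-only AIC with a flag.
#'
#' @param cases registry counts (no `NA`).
#' @param expected_offset expected counts (> 0).
#' @param covariates data frame or matrix of candidate covariates.
#' @return data frame `covariate`, `aic`, `constant`, ascending by AIC.
#' @export
aic_rank <- function(cases, expected_offset, covariates) {
  covariates <- as.data.frame(covariates)
  if (any(is.na(cases))) stop("`cases` must be observed (no NA)", call. = FALSE)
  if (any(expected_offset <= 0)) {
    stop("`expected_offset` must be positive", call. = FALSE)
  }
  off <- log(expected_offset)
  null_aic <- AIC(glm(cases ~ 1 + offset(off), family = poisson()))
  rows <- lapply(names(covariates), function(nm) {
    x <- covariates[[nm]]
    if (sd(x) < 1e-12) {
      data.frame(covariate = nm, aic = null_aic, constant = TRUE)
    } else {
      fit <- glm(cases ~ x + offset(off), family = poisson())
      data.frame(covariate = nm, aic = AIC(fit), constant = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out[order(out$aic, out$covariate), , drop = FALSE]
}

#' Greedy pairwise-correlation exclusion
#'
#' Walks the covariates in the given (AIC-rank) order and drops any whose
#' absolute Pearson correlation with an already-retained covariate
#' exceeds `threshold`. Zero-variance covariates are dropped with an
#' undefined correlation, flagged separately.
#'
#' @param covariates data frame/matrix; column order is the pass order.
#' @param threshold absolute correlation above which a covariate is
#'   dropped (default 0.8).
#' @return list `retained` (character), `dropped` (data frame
#'   `covariate`, `partner`, `r`), `zero_variance` (character).
#' @export
correlation_filter <- function(covariates, threshold = 0.8) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 2) stop("need at least 2 covariates", call. = FALSE)
  retained <- character(0)
  dropped <- list()
  zerovar <- character(0)
  for (nm in names(covariates)) {
    x <- covariates[[nm]]
    if (sd(x) < 1e-12) { zerovar <- c(zerovar, nm); next }
    hit <- FALSE
    for (r_nm in retained) {
      r <- cor(x, covariates[[r_nm]])
      if (abs(r) > threshold) {
        dropped[[length(dropped) + 1]] <-
          data.frame(covariate = nm, partner = r_nm, r = r)
        hit <- TRUE
        break
      }
    }
    if (!hit) retained <- c(retained, nm)
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(covariate = character(0), partner = character(0),
               r = numeric(0))
  list(retained = retained, dropped = dropped, zero_variance = zerovar)
}

vif_values <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iterative variance-inflation-factor exclusion
#'
#' Computes `VIF_j = 1 / (1 - R^2_j)` (each covariate regressed on all
#' others) and repeatedly removes the covariate with the largest VIF
#' while any exceeds `threshold`, recomputing after each removal.
#' Perfect collinearity is reported with an infinite VIF.
#'
#' @param covariates data frame/matrix with at least 2 columns.
#' @param threshold VIF above which removal continues (default 10).
#' @return list `retained` (character), `dropped` (data frame
#'   `covariate`, `vif` at removal time).
#' @export
vif_filter <- function(covariates, threshold = 10) {
  X <- as.matrix(as.data.frame(covariates))
  if (ncol(X) < 2) stop("need at least 2 covariates", call. = FALSE)
  dropped <- list()
  while (ncol(X) >= 2) {
    v <- vif_values(X)
    if (max(v) <= threshold) break
    worst <- which.max(v)
    dropped[[length(dropped) + 1]] <-
      data.frame(covariate = colnames(X)[worst], vif = v[worst])
    X <- X[, -worst, drop = FALSE]
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(covariate = character(0), vif = numeric(0))
  list(retained = colnames(X), dropped = dropped)
}

#' The full covariate-selection funnel
#'
#' AIC ranking, then greedy correlation exclusion in rank order, then
#' iterative VIF exclusion — so the best single predictors survive and
#' the outcome is deterministic.
#'
#' @param cases,expected_offset as [aic_rank()].
#' @param covariates candidate covariate data frame.
#' @param cor_threshold,vif_threshold filter thresholds.
#' @return list of class `screen_report`: `ranked_aic`,
#'   `dropped_correlation`, `dropped_vif`, `zero_variance`, `retained`
#'   (in AIC order).
#' @export
screen_covariates <- function(cases, expected_offset, covariates,
                              cor_threshold = 0.8, vif_threshold = 10) {
  covariates <- as.data.frame(covariates)
  ranked <- aic_rank(cases, expected_offset, covariates)
  ordered <- covariates[, ranked$covariate, drop = FALSE]
  if (ncol(ordered) >= 2) {
    cf <- correlation_filter(ordered, cor_threshold)
  } else {
    cf <- list(retained = names(ordered),
               dropped = data.frame(covariate = character(0),
                                    partner = character(0), r = numeric(0)),
               zero_variance = character(0))
  }
  if (length(cf$retained) >= 2) {
    vf <- vif_filter(ordered[, cf$retained, drop = FALSE], vif_threshold)
  } else {
    vf <- list(retained = cf$retained,
               dropped = data.frame(covariate = character(0),
                                    vif = numeric(0)))
  }
  structure(list(ranked_aic = ranked,
                 dropped_correlation = cf$dropped,
                 dropped_vif = vf$dropped,
                 zero_variance = cf$zero_variance,
                 retained = vf$retained),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("screen_report: %d candidates -> %d retained\n",
              nrow(x$ranked_aic), length(x$retained)))
  cat("retained (AIC order):", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped_correlation)) {
    cat("dropped by correlation:\n"); print(x$dropped_correlation, digits = 3)
  }
  if (nrow(x$dropped_vif)) {
    cat("dropped by VIF:\n"); print(x$dropped_vif, digits = 3)
  }
  invisible(x)
}
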