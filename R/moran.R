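#' Spatial weights from an adjacency list
#'
#' Queen-contiguity neighbor weights, row-standardized by default.
#' Isolated units are kept with an empty (zero-weight) row and flagged.
#'
#' @param adjacency data frame `county_id`, `neighbor_id`; must be
#'   symmetric.
#' @param ids unit ids fixing the order (default: ids present in
#'   `adjacency`).
#' @param standardization `"row"` (rows sum to 1) or `"binary"`.
#' @return list of class `spatial_weights`: `ids`, `neighbors` (index
#'   lists), `weights` (numeric lists), `isolates`, `standardization`.
#' @export
build_weights <- function(adjacency, ids = NULL,
                          standardization = c("row", "binary")) {
  standardization <- match.arg(standardization)
  if (is.null(ids)) {
    ids <- sort(unique(c(adjacency$county_id, adjacency$neighbor_id)))
  }
  pair <- paste(adjacency$county_id, adjacency$neighbor_id)
  rev <- paste(adjacency$neighbor_id, adjacency$county_id)
  if (!all(rev %in% pair)) {
    stop("adjacency is not symmetric", call. = FALSE)
  }
  if (any(adjacency$county_id == adjacency$neighbor_id)) {
    stop("self-neighbors are not allowed", call. = FALSE)
  }
  i <- match(adjacency$county_id, ids)
  j <- match(adjacency$neighbor_id, ids)
  if (any(is.na(i)) || any(is.na(j))) {
    stop("adjacency references ids outside `ids`", call. = FALSE)
  }
  neighbors <- lapply(seq_along(ids), function(k) sort(unique(j[i == k])))
  weights <- lapply(neighbors, function(nb) {
    if (!length(nb)) return(numeric(0))
    if (standardization == "row") rep(1 / length(nb), length(nb)) else
      rep(1, length(nb))
  })
  structure(list(ids = ids, neighbors = neighbors, weights = weights,
                 isolates = ids[lengths(neighbors) == 0L],
                 standardization = standardization),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights (%s): %d units, %d isolates, mean degree %.2f\n",
              x$standardization, length(x$ids), length(x$isolates),
              mean(lengths(x$neighbors))))
  invisible(x)
}

spatial_lag <- function(x, w) {
  vapply(seq_along(x), function(i) {
    nb <- w$neighbors[[i]]
    if (!length(nb)) return(0)
    sum(w$weights[[i]] * x[nb])
  }, numeric(1))
}

weights_s0 <- function(w) sum(vapply(w$weights, sum, numeric(1)))

moran_stat <- function(z, w) {
  s0 <- weights_s0(w)
  n <- length(z)
  n / s0 * sum(z * spatial_lag(z, w)) / sum(z^2)
}

#' Global Moran's I with a permutation test
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' `z = x - mean(x)`. The pseudo p-value counts permutations of `x` whose
#' statistic is at least as extreme as the observed one:
#' `p = (1 + #extreme) / (1 + permutations)`, one-sided "greater" by
#' default.
#'
#' @param x numeric vector with nonzero variance.
#' @param weights a [build_weights()] object of matching length.
#' @param permutations number of random permutations.
#' @param seed integer seed.
#' @param alternative `"greater"`, `"less"`, or `"two.sided"`.
#' @return list `I`, `p_value`, `permutations`, `alternative`,
#'   `expectation` (`-1/(n-1)`).
#' @export
morans_i <- function(x, weights, permutations = 999, seed = 1,
                     alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(x)
  if (n != length(weights$ids)) {
    stop("`x` length must match the weights", call. = FALSE)
  }
  if (sd(x) < 1e-12) stop("`x` has zero variance", call. = FALSE)
  z <- x - mean(x)
  I_obs <- moran_stat(z, weights)
  extreme <- with_seed(seed, {
    vapply(seq_len(permutations), function(p) {
      Ip <- moran_stat(sample(z), weights)
      switch(alternative,
             greater = Ip >= I_obs,
             less = Ip <= I_obs,
             two.sided = abs(Ip) >= abs(I_obs))
    }, logical(1))
  })
  list(I = I_obs, p_value = (1 + sum(extreme)) / (1 + permutations),
       permutations = permutations, alternative = alternative,
       expectation = -1 / (n - 1))
}

#' Local indicators of spatial association (LISA)
#'
#' `local_I_i = z_i * lag_i / (sum z^2 / n)`; the quadrant label follows
#' the signs of the centered value and its spatial lag (HH, LL, LH, HL),
#' and significance uses conditional permutation: the values of all
#' other units are permuted among unit `i`'s neighbors, and the pseudo
#' p-value is one-sided toward the observed local statistic's direction,
#' uncorrected.
#'
#' @param x numeric vector.
#' @param weights a [build_weights()] object.
#' @param permutations conditional permutations per unit.
#' @param alpha significance level (uncorrected).
#' @param seed integer seed.
#' @return list of class `cluster_result`: `global_I`, `pseudo_p` (for
#'   the global test), `local` (data frame `id`, `local_i`, `quadrant`,
#'   `p_value`, `significant`), `permutations`, `alpha`, `seed`.
#' @export
lisa_clusters <- function(x, weights, permutations = 999, alpha = 0.05,
                          seed = 1) {
  n <- length(x)
  if (n != length(weights$ids)) {
    stop("`x` length must match the weights", call. = FALSE)
  }
  if (sd(x) < 1e-12) stop("`x` has zero variance", call. = FALSE)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  lag <- spatial_lag(z, weights)
  local_i <- z * lag / m2
  quadrant <- ifelse(z >= 0, ifelse(lag >= 0, "HH", "HL"),
                     ifelse(lag >= 0, "LH", "LL"))
  glob <- morans_i(x, weights, permutations = permutations, seed = seed)

  p_value <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      nb <- weights$neighbors[[i]]
      if (!length(nb)) return(NA_real_)
      wv <- weights$weights[[i]]
      others <- z[-i]
      k <- length(nb)
      perm_lag <- vapply(seq_len(permutations), function(p) {
        sum(wv * others[sample.int(length(others), k)])
      }, numeric(1))
      perm_local <- z[i] * perm_lag / m2
      extreme <- if (local_i[i] >= 0) sum(perm_local >= local_i[i]) else
        sum(perm_local <= local_i[i])
      (1 + extreme) / (1 + permutations)
    }, numeric(1))
  })
  local <- data.frame(id = weights$ids, local_i = local_i,
                      quadrant = quadrant, p_value = p_value,
                      significant = !is.na(p_value) & p_value < alpha,
                      stringsAsFactors = FALSE)
  structure(list(global_I = glob$I, pseudo_p = glob$p_value, local = local,
                 permutations = permutations, alpha = alpha, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: global I = %.4f (pseudo p = %.4g), %d units\n",
              x$global_I, x$pseudo_p, nrow(x$local)))
  sig <- x$local[x$local$significant, ]
  cat("significant clusters:", paste(names(table(sig$quadrant)),
                                     table(sig$quadrant), collapse = ", "),
      "\n")
  invisible(x)
}

#' Excess risk ratio
#'
#' @param observed observed counts or rates (>= 0).
#' @param expected expected values (>= 0).
#' @return `observed / expected`; `NA` where `expected` is 0.
#' @export
excess_risk <- function(observed, expected) {
  if (any(observed < 0, na.rm = TRUE) || any(expected < 0, na.rm = TRUE)) {
    stop("`observed` and `expected` must be nonnegative", call. = FALSE)
  }
  ifelse(expected > 0, observed / expected, NA_real_)
}

#' Per-province high/low-incidence cluster shares
#'
#' High-incidence counties are significant HH LISA units, low-incidence
#' counties significant LL units; shares are reported both as a
#' percentage of the province's counties and of its resident male
#' population.
#'
#' @param result a [lisa_clusters()] result aligned with `county_table`.
#' @param county_table county data with `county_id`, `province_id` and
#'   `rp_<band>` population columns.
#' @return data frame per province: `n_counties`, `pct_counties_high`,
#'   `pct_population_high`, `pct_counties_low`, `pct_population_low`.
#' @export
cluster_summary <- function(result, county_table) {
  loc <- result$local
  if (!setequal(loc$id, county_table$county_id)) {
    stop("cluster result and county table ids do not match", call. = FALSE)
  }
  idx <- match(county_table$county_id, loc$id)
  hi <- loc$significant[idx] & loc$quadrant[idx] == "HH"
  lo <- loc$significant[idx] & loc$quadrant[idx] == "LL"
  bands <- county_age_bands(county_table)
  pop <- rowSums(county_table[, rp_cols(bands), drop = FALSE])
  out <- do.call(rbind, lapply(split(seq_len(nrow(county_table)),
                                     county_table$province_id),
                               function(i) {
    data.frame(n_counties = length(i),
               pct_counties_high = 100 * mean(hi[i]),
               pct_population_high = 100 * sum(pop[i][hi[i]]) / sum(pop[i]),
               pct_counties_low = 100 * mean(lo[i]),
               pct_population_low = 100 * sum(pop[i][lo[i]]) / sum(pop[i]))
  }))
  out <- cbind(province = rownames(out), out)
  rownames(out) <- NULL
  out$province <- as.character(out$province)
  out
}
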