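#' Generate a province-partitioned county lattice
#'
#' Counties are placed on a jittered unit-spaced planar grid. Provinces are
#' contiguous rectangular blocks tiled into a meta-grid, so that province
#' membership is spatially coherent, as in a real administrative map.
#' Adjacency is queen contiguity on the underlying integer grid.
#'
#' @param n_provinces number of provinces (>= 2).
#' @param counties_per_province counties in each province (>= 1).
#' @param urban_fraction fraction of counties classified urban; the count is
#'   rounded to the nearest integer.
#' @param seed integer seed; the same seed reproduces identical output.
#' @return A list of class `county_geography` with elements `counties`
#'   (data frame: `county_id`, `province_id`, `stratum`, grid `row`/`col`,
#'   centroid `x`/`y`) and `adjacency` (data frame `county_id`,
#'   `neighbor_id`, both directions present).
#' @export
generate_geography <- function(n_provinces, counties_per_province,
                               urban_fraction, seed) {
  stop_if_not_positive(n_provinces, "n_provinces")
  stop_if_not_positive(counties_per_province, "counties_per_province")
  if (n_provinces < 2) stop("`n_provinces` must be >= 2", call. = FALSE)
  stop_if_not_proportion(urban_fraction, "urban_fraction")

  n_provinces <- as.integer(n_provinces)
  cpp <- as.integer(counties_per_province)
  # meta-grid of province blocks
  meta_rows <- max(1L, floor(sqrt(n_provinces)))
  meta_cols <- ceiling(n_provinces / meta_rows)
  # block shape inside a province
  block_rows <- max(1L, floor(sqrt(cpp)))
  block_cols <- ceiling(cpp / block_rows)

  rows <- integer(0); cols <- integer(0); prov <- character(0)
  for (p in seq_len(n_provinces)) {
    mr <- (p - 1L) %/% meta_cols
    mc <- (p - 1L) %% meta_cols
    k <- seq_len(cpp) - 1L
    r <- mr * block_rows + k %/% block_cols
    c <- mc * block_cols + k %% block_cols
    rows <- c(rows, r); cols <- c(cols, c)
    prov <- c(prov, rep(sprintf("p%02d", p), cpp))
  }
  n <- length(rows)
  counties <- with_seed(seed, {
    jit_x <- runif(n, -0.25, 0.25)
    jit_y <- runif(n, -0.25, 0.25)
    n_urban <- round(urban_fraction * n)
    urban_idx <- sample.int(n, n_urban)
    stratum <- rep("rural", n)
    stratum[urban_idx] <- "urban"
    data.frame(
      county_id = sprintf("c%04d", seq_len(n)),
      province_id = prov,
      stratum = stratum,
      row = rows, col = cols,
      x = cols + jit_x, y = rows + jit_y,
      stringsAsFactors = FALSE
    )
  })

  # queen contiguity on the integer grid: cells differing by <= 1 in both axes
  adj_from <- integer(0); adj_to <- integer(0)
  cell <- split(seq_len(n), paste(rows, cols))
  key <- function(r, c) paste(r, c)
  for (i in seq_len(n)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      j <- cell[[key(rows[i] + dr, cols[i] + dc)]]
      if (!is.null(j)) { adj_from <- c(adj_from, i); adj_to <- c(adj_to, j) }
    }
  }
  adjacency <- data.frame(
    county_id = counties$county_id[adj_from],
    neighbor_id = counties$county_id[adj_to],
    stringsAsFactors = FALSE
  )
  structure(list(counties = counties, adjacency = adjacency),
            class = "county_geography")
}

#' @export
print.county_geography <- function(x, ...) {
  cat(sprintf("county_geography: %d counties, %d provinces, %d adjacency pairs\n",
              nrow(x$counties), length(unique(x$counties$province_id)),
              nrow(x$adjacency)))
  invisible(x)
}

# Share of male population in each age band: roughly flat through the working
# ages, tapering above 50 -- a coarse emulation of a national male pyramid.
base_age_shares <- function(bands) {
  mid <- age_band_midpoints(bands)
  w <- exp(-pmax(0, mid - 50) * 0.055)
  w / sum(w)
}

#' Simulate household-registered populations and inter-provincial migration
#'
#' Household-registered (HRP) male populations are drawn per county with
#' lognormal size variation around `base_pop`, split over age bands by a
#' tapering male age pyramid. Migrant stocks flow predominantly from the
#' first half of provinces ("outflow") to the second half ("inflow"),
#' concentrated in working ages (20-49) according to `young_skew`, and
#' destination stocks land mostly in urban strata. Resident populations
#' (RP) are recomputed from HRP and the integer flow table, apportioned to
#' counties within each province proportionally to county HRP, so national
#' person-years are conserved exactly.
#'
#' @param geo a `county_geography`.
#' @param age_bands age band labels covering 0 to 85+ (default 5-year bands).
#' @param base_pop mean county male population (persons).
#' @param migrant_rate migrant stock as a fraction of national HRP, in
#'   `[0, 0.5]`.
#' @param young_skew multiplicative weight (>= 1) applied to ages 20-49 in
#'   the migrant age distribution.
#' @param seed integer seed.
#' @return the input geography with `counties` extended by `hrp_<band>`
#'   and `rp_<band>` columns and a new `migration` element (long table
#'   `origin_province`, `dest_province`, `age_band`, `dest_stratum`,
#'   `count`).
#' @export
simulate_populations_and_migration <- function(geo,
                                               age_bands = default_age_bands(),
                                               base_pop = 250000,
                                               migrant_rate = 0.1,
                                               young_skew = 4,
                                               seed = 1) {
  counties <- geo$counties
  if (migrant_rate < 0 || migrant_rate > 0.5) {
    stop("`migrant_rate` must lie in [0, 0.5]", call. = FALSE)
  }
  if (young_skew < 1) stop("`young_skew` must be >= 1", call. = FALSE)
  lower <- age_band_lower(age_bands)
  if (min(lower) > 0 || max(lower) < 85) {
    stop("`age_bands` must cover ages 0 through 85+", call. = FALSE)
  }

  n <- nrow(counties)
  shares <- base_age_shares(age_bands)
  provinces <- sort(unique(counties$province_id))
  np <- length(provinces)

  out <- with_seed(seed, {
    size <- rlnorm(n, meanlog = log(base_pop) - 0.3^2 / 2, sdlog = 0.3)
    hrp <- outer(size, shares)            # n x bands, fractional
    hrp <- round(hrp)
    storage.mode(hrp) <- "integer"

    prov_hrp <- rowsum(hrp, counties$province_id)          # np x bands
    prov_tot <- rowSums(prov_hrp)
    national <- sum(prov_tot)

    mid <- age_band_midpoints(age_bands)
    age_w <- shares * ifelse(mid >= 20 & mid < 50, young_skew, 1)
    age_w <- age_w / sum(age_w)

    flows <- NULL
    if (migrant_rate > 0 && np >= 2) {
      outflow <- provinces[seq_len(ceiling(np / 2))]
      pairs <- expand.grid(origin = provinces, dest = provinces,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$origin != pairs$dest, ]
      main <- pairs$origin %in% outflow & !(pairs$dest %in% outflow)
      mass <- prov_tot[pairs$origin] * prov_tot[pairs$dest] *
        ifelse(main, 1, 0.08) * rlnorm(nrow(pairs), 0, 0.25)
      mass <- mass / sum(mass) * migrant_rate * national

      # cap origin x age outflow below 90% of the origin's HRP in that band
      flow_age <- outer(mass, age_w)       # pairs x bands
      out_by_prov <- rowsum(flow_age, pairs$origin)
      cap <- 0.9 * prov_hrp[rownames(out_by_prov), , drop = FALSE]
      scale <- pmin(cap / pmax(out_by_prov, 1e-12), 1)
      flow_age <- flow_age * scale[pairs$origin, , drop = FALSE]

      has_urban <- tapply(counties$stratum == "urban", counties$province_id, any)
      has_rural <- tapply(counties$stratum == "rural", counties$province_id, any)
      urb_share <- as.numeric(ifelse(has_urban[pairs$dest],
                                     ifelse(has_rural[pairs$dest], 0.8, 1), 0))

      rows <- list()
      for (s in c("urban", "rural")) {
        frac <- if (s == "urban") urb_share else 1 - urb_share
        cnt <- round(flow_age * frac)
        keep <- which(cnt > 0, arr.ind = TRUE)
        if (nrow(keep)) {
          rows[[s]] <- data.frame(
            origin_province = pairs$origin[keep[, 1]],
            dest_province = pairs$dest[keep[, 1]],
            age_band = age_bands[keep[, 2]],
            dest_stratum = s,
            count = as.integer(cnt[keep]),
            stringsAsFactors = FALSE
          )
        }
      }
      flows <- do.call(rbind, rows)
      rownames(flows) <- NULL
    }
    if (is.null(flows)) {
      flows <- data.frame(origin_province = character(0),
                          dest_province = character(0),
                          age_band = character(0),
                          dest_stratum = character(0),
                          count = integer(0), stringsAsFactors = FALSE)
    }

    # province x band net = inflow - outflow, from the emitted integer table
    net <- matrix(0L, np, length(age_bands),
                  dimnames = list(provinces, age_bands))
    if (nrow(flows)) {
      for (r in seq_len(nrow(flows))) {
        net[flows$dest_province[r], flows$age_band[r]] <-
          net[flows$dest_province[r], flows$age_band[r]] + flows$count[r]
        net[flows$origin_province[r], flows$age_band[r]] <-
          net[flows$origin_province[r], flows$age_band[r]] - flows$count[r]
      }
    }

    # RP per county: HRP plus the province net apportioned by county HRP
    rp <- hrp
    for (p in provinces) {
      idx <- which(counties$province_id == p)
      for (a in seq_along(age_bands)) {
        d <- net[p, a]
        if (d != 0L) {
          add <- apportion_integer(d, hrp[idx, a])
          rp[idx, a] <- rp[idx, a] + add
        }
      }
    }
    if (any(rp < 0)) {
      stop("internal error: negative resident population generated")
    }
    list(hrp = hrp, rp = rp, flows = flows)
  })

  hrp_df <- as.data.frame(out$hrp)
  names(hrp_df) <- hrp_cols(age_bands)
  rp_df <- as.data.frame(out$rp)
  names(rp_df) <- rp_cols(age_bands)
  res <- geo
  res$counties <- cbind(counties, hrp_df, rp_df)
  res$migration <- out$flows
  res
}

#' Simulate standardized county covariates
#'
#' Covariates are independent standard-normal surfaces, optionally smoothed
#' over the queen-contiguity graph to induce positive spatial
#' autocorrelation, with a requested number of near-collinear pairs
#' (Pearson r about 0.97) to exercise the screening funnel. Every emitted
#' column is standardized to mean 0 and sd 1 across counties.
#'
#' @param geo a `county_geography` (or the list returned by
#'   [simulate_populations_and_migration()]).
#' @param n_covariates number of covariate columns (>= 1).
#' @param n_collinear_pairs number of constructed collinear pairs; requires
#'   `2 * n_collinear_pairs <= n_covariates`.
#' @param spatial_corr smoothing strength in `[0, 1)`; 0 leaves surfaces
#'   spatially unstructured.
#' @param seed integer seed.
#' @return the county data frame extended with columns `cov1 ... covN`.
#' @export
simulate_covariates <- function(geo, n_covariates, n_collinear_pairs = 0,
                                spatial_corr = 0, seed = 1) {
  counties <- geo$counties
  adjacency <- geo$adjacency
  stop_if_not_positive(n_covariates, "n_covariates")
  if (n_collinear_pairs < 0 || 2 * n_collinear_pairs > n_covariates) {
    stop("`n_collinear_pairs` must satisfy 2 * pairs <= n_covariates",
         call. = FALSE)
  }
  stop_if_not_proportion(spatial_corr, "spatial_corr")
  n <- nrow(counties)
  idx <- match(adjacency$neighbor_id, counties$county_id)
  nbr <- split(idx, adjacency$county_id)[counties$county_id]

  X <- with_seed(seed, {
    X <- matrix(rnorm(n * n_covariates), n, n_covariates)
    if (spatial_corr > 0) {
      for (pass in 1:3) {
        lag <- apply(X, 2, function(col) {
          vapply(seq_len(n), function(i) {
            nb <- nbr[[i]]
            if (length(nb)) mean(col[nb]) else col[i]
          }, numeric(1))
        })
        X <- (1 - spatial_corr) * X + spatial_corr * lag
      }
    }
    X <- scale(X)
    if (n_collinear_pairs > 0) {
      r <- 0.97
      for (k in seq_len(n_collinear_pairs)) {
        a <- 2L * k - 1L; b <- 2L * k
        X[, b] <- r * X[, a] + sqrt(1 - r^2) * rnorm(n)
      }
      X <- scale(X)
    }
    X
  })
  X <- as.data.frame(X[, , drop = FALSE])
  names(X) <- paste0("cov", seq_len(n_covariates))
  counties <- cbind(counties, X)
  out <- geo
  out$counties <- counties
  out
}

#' Prostate-cancer-like baseline age schedule
#'
#' Incidence per 100,000 person-years per 5-year age band: essentially zero
#' before 40, then rising steeply with age, the canonical shape of prostate
#' cancer incidence.
#' @param bands age band labels.
#' @return named numeric vector, per 100,000 person-years.
#' @export
prostate_age_schedule <- function(bands = default_age_bands()) {
  lower <- age_band_lower(bands)
  rate <- ifelse(lower < 40, 0.05,
                 ifelse(lower < 45, 0.5,
                        ifelse(lower < 50, 2, 2 * exp((lower - 45) * 0.105))))
  setNames(rate, bands)
}

#' Assemble the ground truth used to simulate registry counts
#'
#' Samples a latent Matern (nu = 1) field at county centroids through the
#' SPDE finite-element precision, and bundles it with fixed effects and a
#' baseline age schedule. `beta` names must match covariate columns in
#' `geo$counties`; an `"(Intercept)"` entry is optional and defaults to 0.
#'
#' @param geo county data with covariates.
#' @param beta named fixed-effect vector on the log-rate scale.
#' @param spatial_range Matern correlation range in coordinate units.
#' @param spatial_sd marginal standard deviation of the latent field
#'   (0 switches the field off).
#' @param age_schedule baseline incidence per 100,000 by age band.
#' @param seed integer seed.
#' @param mesh optionally, a prebuilt [build_mesh()] result to reuse.
#' @return list of class `ground_truth`: `beta`, `spatial_range`,
#'   `spatial_sd`, `field_values` (at county centroids), `age_schedule`.
#' @export
make_ground_truth <- function(geo, beta, spatial_range, spatial_sd,
                              age_schedule = prostate_age_schedule(),
                              seed = 1, mesh = NULL) {
  counties <- geo$counties
  stop_if_not_positive(spatial_range, "spatial_range")
  if (spatial_sd < 0) stop("`spatial_sd` must be >= 0", call. = FALSE)
  if (any(age_schedule < 0)) stop("`age_schedule` must be nonnegative",
                                  call. = FALSE)
  field <- rep(0, nrow(counties))
  if (spatial_sd > 0) {
    if (is.null(mesh)) {
      mesh <- build_mesh(cbind(counties$x, counties$y),
                         max_edge = spatial_range / 2,
                         boundary_extension = spatial_range)
    }
    Q <- spde_precision(mesh, spde_hyper(spatial_range, spatial_sd))
    u <- with_seed(seed, sample_gmrf(Q, 1))
    field <- as.numeric(mesh$A %*% u[, 1])
  }
  structure(list(beta = beta, spatial_range = spatial_range,
                 spatial_sd = spatial_sd, field_values = field,
                 age_schedule = age_schedule),
            class = "ground_truth")
}

#' Expected cases from population age structure and a rate schedule
#'
#' @param counties county table with `hrp_<band>` columns.
#' @param schedule named rates per 100,000 person-years by age band.
#' @param population `"hrp"` or `"rp"` age columns.
#' @return numeric vector of expected case counts per county.
#' @export
expected_cases <- function(counties, schedule, population = "hrp") {
  bands <- county_age_bands(counties)
  missing_bands <- setdiff(bands, names(schedule))
  if (length(missing_bands)) {
    stop("schedule lacks age bands: ", paste(missing_bands, collapse = ", "),
         call. = FALSE)
  }
  cols <- paste0(population, "_", bands)
  pop <- as.matrix(counties[, cols, drop = FALSE])
  as.numeric(pop %*% (schedule[bands] / 1e5))
}

#' Simulate registry membership and observed case counts
#'
#' Registry counties are a stratified (urban/rural) random subset; their
#' observed counts are Poisson draws with mean
#' `E_i * exp(beta0 + X beta + u_i)` where `E_i` is the age-schedule
#' expected count from the HRP age structure and `u` the latent field in
#' `truth`. Non-registry counties carry `NA` counts.
#'
#' @param geo county data with covariates (and populations).
#' @param truth a [make_ground_truth()] object.
#' @param registry_fraction fraction of counties with a registry, in (0, 1].
#' @param seed integer seed.
#' @return the county data frame extended with `is_registry`,
#'   `expected_hrp`, and `observed_cases` columns.
#' @export
simulate_registry_cases <- function(geo, truth, registry_fraction, seed = 1) {
  counties <- geo$counties
  if (registry_fraction <= 0 || registry_fraction > 1) {
    stop("`registry_fraction` must lie in (0, 1]", call. = FALSE)
  }
  E <- expected_cases(counties, truth$age_schedule, "hrp")
  beta <- truth$beta
  beta0 <- if ("(Intercept)" %in% names(beta)) beta[["(Intercept)"]] else 0
  slopes <- beta[setdiff(names(beta), "(Intercept)")]
  eta <- rep(beta0, nrow(counties)) + truth$field_values
  if (length(slopes)) {
    miss <- setdiff(names(slopes), names(counties))
    if (length(miss)) {
      stop("truth$beta names not found among covariates: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    eta <- eta + as.matrix(counties[, names(slopes), drop = FALSE]) %*% slopes
  }
  mu <- E * exp(as.numeric(eta))

  out <- with_seed(seed, {
    is_reg <- rep(FALSE, nrow(counties))
    for (s in unique(counties$stratum)) {
      idx <- which(counties$stratum == s)
      k <- round(registry_fraction * length(idx))
      if (registry_fraction == 1) k <- length(idx)
      if (k > 0) is_reg[sample(idx, k)] <- TRUE
    }
    cases <- rep(NA_integer_, nrow(counties))
    cases[is_reg] <- rpois(sum(is_reg), mu[is_reg])
    list(is_reg = is_reg, cases = cases)
  })
  counties$is_registry <- out$is_reg
  counties$expected_hrp <- E
  counties$observed_cases <- out$cases
  res <- geo
  res$counties <- counties
  res
}
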