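#' @importFrom jsonlite write_json read_json toJSON
NULL

stamp_header <- function(seed, hash) {
  sprintf("# mobidence seed=%s config=%s", seed, hash)
}

write_stamped_csv <- function(df, path, seed = NA, hash = "none") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(stamp_header(seed, hash), con)
  write.csv(df, con, row.names = FALSE, na = "")
}

read_stamped_csv <- function(path) {
  read.csv(path, comment.char = "#", check.names = FALSE,
           stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Write the county table, migration table, adjacency and ground truth
#'
#' All CSVs are UTF-8 with a header row, "." decimal separator, and a
#' leading comment line stamping the seed and configuration hash.
#'
#' @param sim a simulated dataset (geography list with `counties`,
#'   `adjacency`, optionally `migration`).
#' @param dir output directory (created if needed).
#' @param truth optional `ground_truth` to serialize as truth.json.
#' @param seed,hash stamp values.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir, truth = NULL, seed = NA, hash = "none") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counties = file.path(dir, "counties.csv"),
             adjacency = file.path(dir, "adjacency.csv"))
  write_stamped_csv(sim$counties, paths["counties"], seed, hash)
  write_stamped_csv(sim$adjacency, paths["adjacency"], seed, hash)
  if (!is.null(sim$migration)) {
    paths["migration"] <- file.path(dir, "migration.csv")
    write_stamped_csv(sim$migration, paths["migration"], seed, hash)
  }
  if (!is.null(truth)) {
    paths["truth"] <- file.path(dir, "truth.json")
    write_json(list(beta = as.list(truth$beta),
                    spatial_range = truth$spatial_range,
                    spatial_sd = truth$spatial_sd,
                    field_values = truth$field_values,
                    age_schedule = as.list(truth$age_schedule),
                    seed = seed, config = hash),
               paths["truth"], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

validate_county_table <- function(counties) {
  fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
  dup <- counties$county_id[duplicated(counties$county_id)]
  if (length(dup)) {
    fail("duplicate county_id at row(s) %s",
         paste(which(counties$county_id %in% dup), collapse = ", "))
  }
  if (any(!nzchar(counties$province_id) | is.na(counties$province_id))) {
    fail("empty province_id at row(s) %s",
         paste(which(!nzchar(counties$province_id) |
                       is.na(counties$province_id)), collapse = ", "))
  }
  bands <- county_age_bands(counties)
  rb <- sub("^rp_", "", grep("^rp_", names(counties), value = TRUE))
  if (!identical(bands, rb)) {
    fail("HRP and RP age-band columns disagree (%s vs %s)",
         paste(bands, collapse = "/"), paste(rb, collapse = "/"))
  }
  pops <- as.matrix(counties[, c(hrp_cols(bands), rp_cols(bands))])
  if (any(is.na(pops)) || any(pops < 0)) {
    bad <- which(apply(is.na(pops) | pops < 0, 1, any))
    fail("negative or missing population counts at row(s) %s",
         paste(head(bad, 5), collapse = ", "))
  }
  hrp_tot <- sum(counties[, hrp_cols(bands)])
  rp_tot <- sum(counties[, rp_cols(bands)])
  if (hrp_tot != rp_tot) {
    fail(paste("national HRP total (%s) != national RP total (%s):",
               "internal migration must conserve national population"),
         hrp_tot, rp_tot)
  }
  if ("is_registry" %in% names(counties) &&
      "observed_cases" %in% names(counties)) {
    mism <- which(xor(counties$is_registry, !is.na(counties$observed_cases)))
    if (length(mism)) {
      fail("observed_cases must be present iff is_registry, row(s) %s",
           paste(head(mism, 5), collapse = ", "))
    }
  }
  invisible(counties)
}

validate_migration <- function(migration, counties = NULL) {
  need <- c("origin_province", "dest_province", "age_band", "dest_stratum",
            "count")
  miss <- setdiff(need, names(migration))
  if (length(miss)) {
    stop("migration table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(migration$count < 0)) {
    stop("negative migrant counts at row(s) ",
         paste(head(which(migration$count < 0), 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(migration$origin_province == migration$dest_province)) {
    stop("intra-province flows at row(s) ",
         paste(head(which(migration$origin_province ==
                            migration$dest_province), 5), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(counties)) {
    bands <- county_age_bands(counties)
    bad <- setdiff(unique(migration$age_band), bands)
    if (length(bad)) {
      stop("migration age bands absent from county table: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    # province-level consistency: RP - HRP == inflow - outflow
    provs <- sort(unique(counties$province_id))
    hrp <- rowsum(rowSums(counties[, hrp_cols(bands)]), counties$province_id)
    rp <- rowsum(rowSums(counties[, rp_cols(bands)]), counties$province_id)
    inflow <- tapply(migration$count, migration$dest_province, sum)
    outflow <- tapply(migration$count, migration$origin_province, sum)
    net <- as.numeric(inflow[provs]); net[is.na(net)] <- 0
    net <- net - ifelse(is.na(outflow[provs]), 0, as.numeric(outflow[provs]))
    off <- which(rp[provs, 1] - hrp[provs, 1] != net)
    if (length(off)) {
      stop("RP - HRP does not equal net migration for province(s): ",
           paste(provs[off], collapse = ", "), call. = FALSE)
    }
  }
  invisible(migration)
}

#' Read and validate the pipeline input tables
#'
#' @param counties_path,migration_path,adjacency_path,standard_path file
#'   paths; migration, adjacency and the standard schedule are optional.
#' @return list `counties`, `migration`, `adjacency`, `standard` (data
#'   frame `age_band`, `standard_rate`, `standard_weight` or `NULL`).
#' @export
read_inputs <- function(counties_path, migration_path = NULL,
                        adjacency_path = NULL, standard_path = NULL) {
  counties <- read_stamped_csv(counties_path)
  if ("is_registry" %in% names(counties)) {
    counties$is_registry <- as.logical(counties$is_registry)
  }
  validate_county_table(counties)
  migration <- NULL
  if (!is.null(migration_path)) {
    migration <- read_stamped_csv(migration_path)
    validate_migration(migration, counties)
  }
  adjacency <- NULL
  if (!is.null(adjacency_path)) {
    adjacency <- read_stamped_csv(adjacency_path)
    if (!all(c("county_id", "neighbor_id") %in% names(adjacency))) {
      stop("adjacency needs columns county_id, neighbor_id", call. = FALSE)
    }
  }
  standard <- NULL
  if (!is.null(standard_path)) {
    standard <- read_stamped_csv(standard_path)
    need <- c("age_band", "standard_rate", "standard_weight")
    miss <- setdiff(need, names(standard))
    if (length(miss)) {
      stop("standard schedule lacks column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  list(counties = counties, migration = migration, adjacency = adjacency,
       standard = standard)
}

#' Default configuration of the end-to-end pipeline
#'
#' @param seed master seed; every stage's randomness derives from it.
#' @param output_dir where outputs are written.
#' @return nested configuration list (see [run_pipeline()]).
#' @export
default_config <- function(seed = 1, output_dir = tempfile("mobidence_run_")) {
  list(
    seed = seed,
    output_dir = output_dir,
    simulate = list(
      n_provinces = 6, counties_per_province = 40, urban_fraction = 0.4,
      base_pop = 250000, migrant_rate = 0.15, young_skew = 4,
      n_covariates = 6, n_collinear_pairs = 1, spatial_corr = 0.3,
      beta = c("(Intercept)" = 0, cov1 = 0.3),
      spatial_range = 3, spatial_sd = 0.4,
      registry_fraction = 0.3
    ),
    model = list(
      covariates = NULL,          # NULL: use the screened retained set
      max_edge = 2, boundary_extension = 3,
      range_grid = c(1, 10, 5), sill_grid = c(0.01, 5, 5),
      criteria_draws = 1000
    ),
    adjust = list(basis = "origin"),
    cluster = list(permutations = 999, alpha = 0.05,
                   rates_column = "rp_crude")
  )
}

grid_from_spec <- function(g) {
  if (length(g) == 3 && g[3] == round(g[3]) && g[3] >= 1) {
    exp(seq(log(g[1]), log(g[2]), length.out = g[3]))
  } else {
    as.numeric(g)
  }
}

#' Run the full estimation pipeline on synthetic or supplied data
#'
#' Stages, in order: simulate (or load) the county data; screen the
#' covariates; fit the spatial model to registry counts; reallocate
#' cases by migrant weights to the resident population and build the
#' provincial difference tables with indirect age standardization; and
#' detect spatial clusters of the resident-population incidence. Every
#' output CSV carries the seed and a configuration hash; rerunning with
#' an identical configuration reproduces identical files.
#'
#' @param config a configuration list ([default_config()]) or the path
#'   of a YAML file with the same structure. Supply
#'   `config$inputs$counties` (etc.) to skip simulation.
#' @return invisibly, a list with the in-memory results of every stage
#'   and the output paths.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  config <- utils::modifyList(base, config)
  if (!is.null(config$simulate$beta)) {
    config$simulate$beta <- unlist(config$simulate$beta)
  }
  seed <- config$seed
  hash_cfg <- config
  hash_cfg$output_dir <- NULL   # the fingerprint covers analysis settings only
  hash <- fnv1a32(toJSON(hash_cfg, auto_unbox = TRUE, digits = NA,
                         force = TRUE))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$output_dir, "pipeline.log")
  cat(stamp_header(seed, hash), "\n", file = logf)
  log_stage <- function(...) {
    cat(sprintf(...), "\n", file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    log_stage("stage %s: start", name)
    res <- tryCatch(expr, error = function(e) {
      log_stage("stage %s: FAILED (%s)", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log_stage("stage %s: done", name)
    res
  }

  # ---- data: simulate or load ------------------------------------------
  truth <- NULL
  if (!is.null(config$inputs$counties)) {
    dat <- stage("load", read_inputs(config$inputs$counties,
                                     config$inputs$migration,
                                     config$inputs$adjacency,
                                     config$inputs$standard))
    counties <- dat$counties
    migration <- dat$migration
    adjacency <- dat$adjacency
    standard <- dat$standard
  } else {
    sm <- config$simulate
    simres <- stage("simulate", {
      geo <- generate_geography(sm$n_provinces, sm$counties_per_province,
                                sm$urban_fraction, seed = seed)
      geo <- simulate_populations_and_migration(
        geo, base_pop = sm$base_pop, migrant_rate = sm$migrant_rate,
        young_skew = sm$young_skew, seed = seed + 1)
      geo <- simulate_covariates(geo, sm$n_covariates, sm$n_collinear_pairs,
                                 sm$spatial_corr, seed = seed + 2)
      tr <- make_ground_truth(geo, beta = sm$beta,
                              spatial_range = sm$spatial_range,
                              spatial_sd = sm$spatial_sd,
                              seed = seed + 3)
      list(sim = simulate_registry_cases(geo, tr, sm$registry_fraction,
                                         seed = seed + 4),
           truth = tr)
    })
    sim <- simres$sim
    truth <- simres$truth
    counties <- sim$counties
    migration <- sim$migration
    adjacency <- sim$adjacency
    standard <- NULL
    write_dataset(sim, config$output_dir, truth = truth, seed = seed,
                  hash = hash)
  }
  bands <- county_age_bands(counties)
  schedule <- if (!is.null(standard)) {
    setNames(standard$standard_rate, standard$age_band)
  } else {
    prostate_age_schedule(bands)
  }
  std_weights <- if (!is.null(standard)) {
    w <- setNames(standard$standard_weight, standard$age_band)
    w / sum(w)
  } else {
    who_standard_weights(bands)
  }

  reg <- which(counties$is_registry)
  E <- if ("expected_hrp" %in% names(counties)) counties$expected_hrp else
    expected_cases(counties, schedule, "hrp")

  # ---- screen ----------------------------------------------------------
  cov_cols <- grep("^cov", names(counties), value = TRUE)
  screen <- stage("screen", screen_covariates(
    counties$observed_cases[reg], E[reg],
    counties[reg, cov_cols, drop = FALSE]))
  write_stamped_csv(screen_report_table(screen),
                    file.path(config$output_dir, "screen_report.csv"),
                    seed, hash)

  # ---- fit -------------------------------------------------------------
  use_cov <- config$model$covariates
  if (is.null(use_cov)) use_cov <- screen$retained
  md <- config$model
  fitres <- stage("fit", {
    mesh <- build_mesh(cbind(counties$x, counties$y), md$max_edge,
                       md$boundary_extension)
    hrp_pop <- rowSums(counties[, hrp_cols(bands)])
    fit <- spde_fit(counties$observed_cases, E,
                    X = as.matrix(counties[, use_cov, drop = FALSE]),
                    mesh = mesh,
                    range_grid = grid_from_spec(md$range_grid),
                    sill_grid = grid_from_spec(md$sill_grid),
                    population = hrp_pop)
    crit <- model_criteria(fit, n_draws = md$criteria_draws, seed = seed + 5)
    cover <- validate_coverage(fit, n_draws = md$criteria_draws,
                               seed = seed + 6)
    list(fit = fit, criteria = crit, coverage = cover, mesh = mesh)
  })
  fit <- fitres$fit
  hp <- hyper_posterior_mean(fit)
  write_json(list(seed = seed, config = hash,
                  covariates = use_cov,
                  criteria = fitres$criteria[c("dic", "waic", "mll", "p_d",
                                               "p_waic")],
                  coverage_95bci = fitres$coverage$coverage,
                  hyper = as.list(hp),
                  beta = fit$beta),
             file.path(config$output_dir, "fit.json"),
             auto_unbox = TRUE, digits = NA, dataframe = "rows")
  rates_out <- cbind(data.frame(county_id = counties$county_id), fit$rates)
  write_stamped_csv(rates_out,
                    file.path(config$output_dir, "county_rates.csv"),
                    seed, hash)

  # ---- adjust + standardize -------------------------------------------
  adj <- stage("adjust", {
    fitted_cases <- fit$rates$fitted_cases
    hrp_cases <- aggregate_cases(counties, fitted_cases)
    hrp_pop <- population_table(counties, "hrp", bands)
    rp_pop <- population_table(counties, "rp", bands)
    national_crude <- sum(fitted_cases) / sum(hrp_pop$population) * 1e5
    # rescale the baseline age schedule to the model-based national level
    shares <- colSums(counties[, hrp_cols(bands)]) /
      sum(counties[, hrp_cols(bands)])
    national_schedule <- schedule[bands] * national_crude /
      sum(shares * schedule[bands])
    basis <- config$adjust$basis
    rates <- if (basis == "national") {
      data.frame(age_band = bands, rate = as.numeric(national_schedule),
                 stringsAsFactors = FALSE)
    } else {
      prov_crude <- merge(
        aggregate(cases ~ province, data = hrp_cases, sum),
        aggregate(population ~ province, data = hrp_pop, sum))
      prov_crude$crude <- crude_rates(prov_crude$cases,
                                      prov_crude$population)
      province_age_schedules(national_schedule,
                             prov_crude[, c("province", "crude")],
                             national_crude)
    }
    flows <- if (!is.null(migration)) migration else
      data.frame(origin_province = character(0),
                 dest_province = character(0), age_band = character(0),
                 dest_stratum = character(0), count = numeric(0))
    adjusted <- adjust_cases(hrp_cases, flows, rates, basis = basis)
    tab <- difference_table(
      data.frame(province = adjusted$province, stratum = adjusted$stratum,
                 cases = adjusted$hrp_cases),
      data.frame(province = adjusted$province, stratum = adjusted$stratum,
                 cases = adjusted$rp_cases),
      hrp_pop, rp_pop)
    # indirect ASIR per province x stratum on the resident population
    rp_age <- rp_age_matrix(counties, bands)
    tabk <- paste(tab$province, tab$stratum)
    asir <- indirect_asir(tab$rp_cases, rp_age[tabk, , drop = FALSE],
                          schedule, std_weights)
    tab$sir <- asir$sir
    tab$asir <- asir$asir
    list(table = tab, rates = rates, adjusted = adjusted)
  })
  tab <- adj$table
  write_stamped_csv(cbind(as.data.frame(tab)[tab$stratum != "all", ]),
                    file.path(config$output_dir, "table1.csv"), seed, hash)
  write_stamped_csv(as.data.frame(tab),
                    file.path(config$output_dir, "table2.csv"), seed, hash)

  # ---- cluster ---------------------------------------------------------
  clus <- stage("cluster", {
    w <- build_weights(adjacency, ids = counties$county_id)
    # county resident-population incidence: model-based cases scaled by the
    # province-stratum RP/HRP case ratio, over the RP denominator
    key <- paste(counties$province_id, counties$stratum)
    tabk <- paste(tab$province, tab$stratum)
    ratio <- tab$rp_cases[match(key, tabk)] /
      pmax(tab$hrp_cases[match(key, tabk)], 1e-12)
    rp_pop_cty <- rowSums(counties[, rp_cols(bands)])
    rp_rate <- crude_rates(fit$rates$fitted_cases * ratio, rp_pop_cty)
    x <- switch(config$cluster$rates_column,
                rp_crude = rp_rate,
                hrp_crude = fit$rates$rate,
                stop("unknown cluster rates_column"))
    lisa <- lisa_clusters(x, w, permutations = config$cluster$permutations,
                          alpha = config$cluster$alpha, seed = seed + 7)
    summ <- cluster_summary(lisa, counties)
    list(lisa = lisa, summary = summ, variable = x)
  })
  cl <- clus$lisa$local
  names(cl)[names(cl) == "id"] <- "county_id"
  write_stamped_csv(cl, file.path(config$output_dir, "clusters.csv"),
                    seed, hash)
  write_stamped_csv(clus$summary,
                    file.path(config$output_dir, "summary.csv"), seed, hash)
  write_json(list(seed = seed, config = hash,
                  global_moran_i = clus$lisa$global_I,
                  pseudo_p = clus$lisa$pseudo_p),
             file.path(config$output_dir, "moran.json"),
             auto_unbox = TRUE, digits = NA)
  log_stage("pipeline complete")

  invisible(list(config = config, hash = hash, counties = counties,
                 migration = migration, truth = truth, screen = screen,
                 fit = fit, criteria = fitres$criteria,
                 coverage = fitres$coverage, table = tab,
                 cluster = clus, output_dir = config$output_dir))
}

screen_report_table <- function(screen) {
  rows <- data.frame(covariate = screen$ranked_aic$covariate,
                     disposition = "retained",
                     statistic = screen$ranked_aic$aic,
                     stringsAsFactors = FALSE)
  rows$disposition[rows$covariate %in%
                     screen$dropped_correlation$covariate] <- "dropped_correlation"
  rows$disposition[rows$covariate %in% screen$dropped_vif$covariate] <-
    "dropped_vif"
  rows$disposition[rows$covariate %in% screen$zero_variance] <-
    "zero_variance"
  rows
}

aggregate_cases <- function(counties, cases) {
  df <- aggregate(cases,
                  by = list(province = counties$province_id,
                            stratum = counties$stratum), FUN = sum)
  names(df)[3] <- "cases"
  df
}

population_table <- function(counties, which, bands) {
  pop <- rowSums(counties[, paste0(which, "_", bands)])
  df <- aggregate(pop, by = list(province = counties$province_id,
                                 stratum = counties$stratum), FUN = sum)
  names(df)[3] <- "population"
  df
}

# RP person-years by age band for each province x stratum cell (and "all")
rp_age_matrix <- function(counties, bands) {
  m <- as.matrix(counties[, rp_cols(bands)])
  colnames(m) <- bands
  key <- paste(counties$province_id, counties$stratum)
  bystrat <- rowsum(m, key)
  byprov <- rowsum(m, paste(counties$province_id, "all"))
  rbind(bystrat, byprov)
}
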