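#' Provincial net migrant counts
#'
#' Net migrants per province as the difference between resident (RP) and
#' household-registered (HRP) totals: positive values mark inflow
#' provinces, negative values outflow provinces.
#'
#' @param populations data frame with columns `province`, `hrp`, `rp`
#'   (province totals, persons).
#' @return data frame `province`, `net` (`rp - hrp`).
#' @export
net_migrants <- function(populations) {
  need <- c("province", "hrp", "rp")
  miss <- setdiff(need, names(populations))
  if (length(miss)) {
    stop("`populations` lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- populations$province[is.na(populations$hrp) | is.na(populations$rp)]
  if (length(bad)) {
    stop("missing population totals for province(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  data.frame(province = populations$province,
             net = populations$rp - populations$hrp,
             stringsAsFactors = FALSE)
}

# resolve the age-specific rate (per 100,000) that prices a flow entry;
# basis "origin"/"destination" selects the province whose schedule applies
flow_rates <- function(flows, rates, basis) {
  if (basis == "national") {
    if (!all(c("age_band", "rate") %in% names(rates))) {
      stop("national `rates` needs columns age_band, rate", call. = FALSE)
    }
    r <- rates$rate[match(flows$age_band, rates$age_band)]
  } else {
    if (!all(c("province", "age_band", "rate") %in% names(rates))) {
      stop("per-province `rates` needs columns province, age_band, rate",
           call. = FALSE)
    }
    prov <- if (basis == "origin") flows$origin_province else
      flows$dest_province
    key <- paste(prov, flows$age_band)
    r <- rates$rate[match(key, paste(rates$province, rates$age_band))]
  }
  if (any(is.na(r))) {
    stop("rate schedule does not cover all flow age bands/provinces",
         call. = FALSE)
  }
  r
}

#' Reallocate incident cases between registered and resident populations
#'
#' Expected cases carried by each migrant stock entry are
#' `count * rate / 100,000`. The removal leg — out-migrant cases taken
#' out of the origin's registered count — is always priced at the
#' origin province's age-specific schedule (those cases are embedded in
#' the origin's registry-based estimate), or at the common national
#' schedule under `basis = "national"`. The addition leg — in-migrant
#' cases credited to the destination, in the entry's destination
#' stratum — is priced at the `basis` schedule: origin (default; risk
#' travels with the migrant, and the two legs then cancel exactly),
#' destination (migrants take on destination risk; national totals are
#' then generally not conserved when schedules differ), or national.
#' Origin-side removals are spread over the origin's strata
#' proportionally to the origin's stratum case shares.
#'
#' @param hrp_cases data frame `province`, `stratum`, `cases`
#'   (household-registration-based incident cases).
#' @param flows migrant stock table (`origin_province`, `dest_province`,
#'   `age_band`, `dest_stratum`, `count`).
#' @param rates age-specific incidence schedule per 100,000:
#'   `age_band`, `rate` for `basis = "national"`, plus a `province`
#'   column otherwise.
#' @param basis whose schedule prices migrant person-years.
#' @return data frame `province`, `stratum`, `hrp_cases`, `rp_cases`,
#'   with an attribute `floored` listing cells floored at zero (possible
#'   under extreme inputs).
#' @export
adjust_cases <- function(hrp_cases, flows, rates,
                         basis = c("origin", "destination", "national")) {
  basis <- match.arg(basis)
  need <- c("province", "stratum", "cases")
  if (!all(need %in% names(hrp_cases))) {
    stop("`hrp_cases` needs columns province, stratum, cases", call. = FALSE)
  }
  out <- hrp_cases[, need]
  names(out)[3] <- "hrp_cases"
  out$rp_cases <- out$hrp_cases

  if (nrow(flows)) {
    unknown <- setdiff(unique(c(flows$origin_province, flows$dest_province)),
                       unique(out$province))
    if (length(unknown)) {
      stop("flows reference unknown province(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(flows$origin_province == flows$dest_province)) {
      stop("flows must be inter-provincial (origin != destination)",
           call. = FALSE)
    }
    mc_add <- flows$count * flow_rates(flows, rates, basis) / 1e5
    removal_basis <- if (basis == "national") "national" else "origin"
    mc_rem <- flows$count * flow_rates(flows, rates, removal_basis) / 1e5

    # destination gains, in the entry's destination stratum
    in_key <- paste(flows$dest_province, flows$dest_stratum)
    gains <- tapply(mc_add, in_key, sum)
    out_key <- paste(out$province, out$stratum)
    add <- as.numeric(gains[out_key]); add[is.na(add)] <- 0

    # origin losses, split over origin strata by HRP case shares
    out_tot <- tapply(mc_rem, flows$origin_province, sum)
    prov_cases <- tapply(out$hrp_cases, out$province, sum)
    share <- ifelse(prov_cases[out$province] > 0,
                    out$hrp_cases / prov_cases[out$province], NA)
    # provinces with zero total cases: split losses evenly over strata
    nstrat <- tapply(out$stratum, out$province, length)
    share[is.na(share)] <- 1 / nstrat[out$province[is.na(share)]]
    loss_tot <- as.numeric(out_tot[out$province]); loss_tot[is.na(loss_tot)] <- 0
    remove <- loss_tot * as.numeric(share)

    rp <- out$hrp_cases + add - remove
    floored <- which(rp < 0)
    if (length(floored)) {
      warning(sprintf("%d province-stratum cells floored at zero cases",
                      length(floored)))
      rp[floored] <- 0
    }
    out$rp_cases <- rp
    attr(out, "floored") <- out[floored, c("province", "stratum")]
  }
  out
}

#' Crude incidence per 100,000
#'
#' @param cases case counts.
#' @param male_population matching denominators (person-years).
#' @return `cases / male_population * 100,000`; `NA` where the
#'   denominator is zero.
#' @export
crude_rates <- function(cases, male_population) {
  ifelse(male_population > 0, cases / male_population * 1e5, NA_real_)
}

#' Province x stratum difference table for HRP vs RP incidence
#'
#' The machine form of the printed provincial difference tables: one row
#' per province and stratum (urban, rural, all) with HRP and RP cases,
#' `diff = rp - hrp`, `diff_pct = 100 * diff / hrp`, and crude rates per
#' 100,000 against the matching populations. The footer attribute
#' carries, per stratum column, the emigrating total (sum of negative
#' diffs, as a magnitude), the immigrating total (sum of positive
#' diffs), and national totals; `immigrating - emigrating` equals the
#' national net case difference by construction.
#'
#' @param hrp_cases,rp_cases data frames `province`, `stratum`, `cases`.
#' @param hrp_pop,rp_pop optional matching population data frames
#'   (`province`, `stratum`, `population`); when supplied, crude-rate
#'   columns are added.
#' @return data frame of class `incidence_report` with attribute
#'   `footer`.
#' @export
difference_table <- function(hrp_cases, rp_cases, hrp_pop = NULL,
                             rp_pop = NULL) {
  key <- function(d) paste(d$province, d$stratum)
  if (!setequal(key(hrp_cases), key(rp_cases))) {
    stop("HRP and RP case tables must share (province, stratum) keys",
         call. = FALSE)
  }
  base <- hrp_cases[, c("province", "stratum")]
  base$hrp_cases <- hrp_cases$cases
  base$rp_cases <- rp_cases$cases[match(key(base), key(rp_cases))]

  # add the province "all" rows
  all_h <- tapply(base$hrp_cases, base$province, sum)
  all_r <- tapply(base$rp_cases, base$province, sum)
  allrows <- data.frame(province = names(all_h), stratum = "all",
                        hrp_cases = as.numeric(all_h),
                        rp_cases = as.numeric(all_r),
                        stringsAsFactors = FALSE)
  tab <- rbind(base, allrows)
  tab$diff <- tab$rp_cases - tab$hrp_cases
  tab$diff_pct <- ifelse(tab$hrp_cases > 0, 100 * tab$diff / tab$hrp_cases,
                         ifelse(tab$rp_cases > 0, NA_real_, 0))

  attach_pop <- function(tab, pop, prefix) {
    if (is.null(pop)) return(tab)
    pk <- paste(pop$province, pop$stratum)
    allp <- tapply(pop$population, pop$province, sum)
    lookup <- c(setNames(pop$population, pk),
                setNames(as.numeric(allp), paste(names(allp), "all")))
    p <- lookup[paste(tab$province, tab$stratum)]
    tab[[paste0(prefix, "_pop")]] <- as.numeric(p)
    tab[[paste0(prefix, "_crude")]] <-
      crude_rates(tab[[paste0(prefix, "_cases")]], as.numeric(p))
    tab
  }
  tab <- attach_pop(tab, hrp_pop, "hrp")
  tab <- attach_pop(tab, rp_pop, "rp")

  footer <- do.call(rbind, lapply(unique(tab$stratum), function(s) {
    d <- tab$diff[tab$stratum == s]
    data.frame(stratum = s,
               emigrating = sum(-d[d < 0]),
               immigrating = sum(d[d > 0]),
               hrp_total = sum(tab$hrp_cases[tab$stratum == s]),
               rp_total = sum(tab$rp_cases[tab$stratum == s]))
  }))
  footer$net <- footer$immigrating - footer$emigrating
  footer$absolute_discrepancy <- footer$immigrating + footer$emigrating
  attr(tab, "footer") <- footer
  class(tab) <- c("incidence_report", "data.frame")
  tab
}

#' @export
print.incidence_report <- function(x, digits = 1, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, ...)
  cat("\nfooter:\n")
  print(attr(x, "footer"), digits = 6)
  invisible(x)
}

#' Indirect age standardization: expected cases, SIR and indirect ASIR
#'
#' `expected = sum_a n_a * s_a / 100,000` prices the local age structure
#' `n_a` at the standard schedule `s_a`; `SIR = observed / expected`;
#' the indirectly standardized rate is `ASIR = SIR * C_std` where
#' `C_std = sum_a w_a * s_a` is the standard population's crude rate per
#' 100,000.
#'
#' @param observed_cases observed counts (scalar or vector of units).
#' @param local_age_structure person-years by age band: a vector, or a
#'   matrix with one row per unit.
#' @param standard_schedule named standard incidence per 100,000 by band.
#' @param standard_weights standard population age weights (sum 1),
#'   same bands.
#' @return data frame `expected`, `sir`, `asir`; `sir`/`asir` are 0 when
#'   `observed = 0` and `NA` when `expected = 0` with observed cases.
#' @export
indirect_asir <- function(observed_cases, local_age_structure,
                          standard_schedule, standard_weights) {
  n <- local_age_structure
  if (is.null(dim(n))) n <- matrix(n, nrow = 1)
  bands <- names(standard_schedule)
  if (!is.null(colnames(n))) {
    miss <- setdiff(colnames(n), bands)
    if (length(miss)) {
      stop("standard schedule lacks bands: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    s <- standard_schedule[colnames(n)]
    w <- standard_weights[colnames(n)]
  } else {
    if (ncol(n) != length(standard_schedule)) {
      stop("age-band mismatch between structure and schedule", call. = FALSE)
    }
    s <- as.numeric(standard_schedule)
    w <- as.numeric(standard_weights)
  }
  if (abs(sum(w) - 1) > 1e-6) {
    stop("`standard_weights` must sum to 1", call. = FALSE)
  }
  expected <- as.numeric(n %*% (s / 1e5))
  c_std <- sum(w * s)
  sir <- ifelse(observed_cases == 0, 0,
                ifelse(expected > 0, observed_cases / expected, NA_real_))
  data.frame(expected = expected, sir = sir, asir = sir * c_std)
}

#' Standard population age weights (WHO World Standard)
#'
#' The WHO World Standard Population shares collapsed to 5-year bands
#' with a terminal 85+ band, normalized to sum to 1.
#'
#' @param bands age band labels (default 0-4 ... 85+).
#' @return named numeric weights summing to 1.
#' @export
who_standard_weights <- function(bands = default_age_bands()) {
  w <- c(8.86, 8.69, 8.60, 8.47, 8.22, 7.93, 7.61, 7.15, 6.59, 6.04,
         5.37, 4.55, 3.72, 2.96, 2.21, 1.52, 0.91, 0.635)
  if (length(bands) != length(w)) {
    stop("WHO standard weights are defined for the default 18 bands",
         call. = FALSE)
  }
  setNames(w / sum(w), bands)
}

#' Derive per-province age schedules from a national schedule
#'
#' Proportional-age-structure assumption: each province's age-specific
#' rates are the national schedule scaled by the ratio of the province's
#' crude rate to the national crude rate.
#'
#' @param national named national rates per 100,000 by age band.
#' @param province_crude data frame `province`, `crude` (per 100,000).
#' @param national_crude national crude rate per 100,000.
#' @return data frame `province`, `age_band`, `rate`.
#' @export
province_age_schedules <- function(national, province_crude, national_crude) {
  stop_if_not_positive(national_crude, "national_crude")
  do.call(rbind, lapply(seq_len(nrow(province_crude)), function(i) {
    data.frame(province = province_crude$province[i],
               age_band = names(national),
               rate = as.numeric(national) *
                 province_crude$crude[i] / national_crude,
               stringsAsFactors = FALSE)
  }))
}
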