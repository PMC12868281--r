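two_province_cases <- function(au = 100, ar = 100, bu = 100, br = 100) {
  data.frame(province = c("A", "A", "B", "B"),
             stratum = c("urban", "rural", "urban", "rural"),
             cases = c(au, ar, bu, br), stringsAsFactors = FALSE)
}

test_that("net migrants are RP minus HRP with exact conservation", {
  pops <- data.frame(province = c("A", "B"), hrp = c(1e6, 1e6),
                     rp = c(1.01e6, 0.99e6))
  net <- net_migrants(pops)
  expect_equal(net$net, c(10000, -10000))
  expect_equal(sum(net$net), 0)
  same <- data.frame(province = "A", hrp = 5, rp = 5)
  expect_equal(net_migrants(same)$net, 0)
  bad <- data.frame(province = c("A", "B"), hrp = c(1, NA), rp = c(1, 2))
  expect_error(net_migrants(bad), "B")
})

test_that("a single flow moves exactly its expected cases", {
  hrp <- two_province_cases()
  flows <- data.frame(origin_province = "A", dest_province = "B",
                      age_band = "60-64", dest_stratum = "urban",
                      count = 10000, stringsAsFactors = FALSE)
  rates <- data.frame(age_band = "60-64", rate = 100)
  adj <- adjust_cases(hrp, flows, rates, basis = "national")
  # 10,000 person-years at 100/100,000 = 10 expected cases
  expect_equal(adj$rp_cases[adj$province == "B" & adj$stratum == "urban"],
               110)
  # origin loses 10, split evenly because case shares are equal
  expect_equal(adj$rp_cases[adj$province == "A"], c(95, 95))
  expect_equal(sum(adj$rp_cases), sum(adj$hrp_cases))
})

test_that("empty flows leave the case table unchanged", {
  hrp <- two_province_cases(80, 20, 50, 150)
  empty <- data.frame(origin_province = character(0),
                      dest_province = character(0),
                      age_band = character(0), dest_stratum = character(0),
                      count = numeric(0))
  adj <- adjust_cases(hrp, empty, data.frame(age_band = "60-64", rate = 1))
  expect_equal(adj$rp_cases, adj$hrp_cases)
})

test_that("national basis conserves cases; destination basis does not", {
  for (s in 1:3) {
    set.seed(s)
    provs <- LETTERS[1:4]
    hrp <- expand.grid(province = provs, stratum = c("urban", "rural"),
                       stringsAsFactors = FALSE)
    hrp$cases <- rpois(nrow(hrp), 200)
    pairs <- expand.grid(origin_province = provs, dest_province = provs,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$origin_province != pairs$dest_province, ]
    flows <- data.frame(pairs,
                        age_band = sample(c("55-59", "60-64"), nrow(pairs),
                                          TRUE),
                        dest_stratum = sample(c("urban", "rural"),
                                              nrow(pairs), TRUE),
                        count = rpois(nrow(pairs), 5000))
    nat <- data.frame(age_band = c("55-59", "60-64"), rate = c(60, 120))
    prov_rates <- expand.grid(province = provs,
                              age_band = c("55-59", "60-64"),
                              stringsAsFactors = FALSE)
    set.seed(s + 10)
    prov_rates$rate <- runif(nrow(prov_rates), 30, 200)

    adj_nat <- adjust_cases(hrp, flows, nat, basis = "national")
    expect_equal(sum(adj_nat$rp_cases), sum(adj_nat$hrp_cases),
                 tolerance = 1e-9)
    # origin pricing: removal and addition legs cancel exactly
    adj_org <- adjust_cases(hrp, flows, prov_rates, basis = "origin")
    expect_equal(sum(adj_org$rp_cases), sum(adj_org$hrp_cases),
                 tolerance = 1e-9)
    # destination pricing values the two legs differently
    adj_dst <- adjust_cases(hrp, flows, prov_rates, basis = "destination")
    expect_gt(abs(sum(adj_dst$rp_cases) - sum(adj_dst$hrp_cases)), 1e-6)
  }
  expect_error(
    adjust_cases(two_province_cases(),
                 data.frame(origin_province = "A", dest_province = "Z",
                            age_band = "60-64", dest_stratum = "urban",
                            count = 1),
                 data.frame(age_band = "60-64", rate = 1),
                 basis = "national"),
    "Z")
})

test_that("crude rates follow the definition with a zero-denominator sentinel", {
  expect_equal(crude_rates(0, 1000), 0)
  expect_equal(crude_rates(50, 600000), 8.3333, tolerance = 1e-4)
  expect_true(is.na(crude_rates(3, 0)))
  expect_equal(crude_rates(c(1, 2), c(1e5, 2e5)), c(1, 1))
})

test_that("difference table reproduces printed provincial cells", {
  # Guangdong and Henan, urban/rural cells as published
  hrp <- data.frame(province = c("Guangdong", "Guangdong", "Henan", "Henan"),
                    stratum = c("urban", "rural", "urban", "rural"),
                    cases = c(2928, 1901, 928, 2229))
  rp <- data.frame(province = hrp$province, stratum = hrp$stratum,
                   cases = c(3274, 2024, 883, 2001))
  tab <- difference_table(hrp, rp)
  gd <- tab[tab$province == "Guangdong" & tab$stratum == "all", ]
  expect_equal(gd$hrp_cases, 4829)
  expect_equal(gd$rp_cases, 5298)
  expect_equal(gd$diff, 469)
  expect_equal(round(gd$diff_pct, 1), 9.7)
  hn <- tab[tab$province == "Henan" & tab$stratum == "all", ]
  expect_equal(hn$diff, -273)
  expect_equal(round(hn$diff_pct, 1), -8.6)
  foot <- attr(tab, "footer")
  allrow <- foot[foot$stratum == "all", ]
  expect_equal(allrow$immigrating - allrow$emigrating,
               sum(tab$diff[tab$stratum == "all"]))

  # equal inputs: all differences zero
  t0 <- difference_table(hrp, hrp)
  expect_true(all(t0$diff == 0))
  expect_true(all(t0$diff_pct == 0))

  # undefined percentage sentinel
  h0 <- data.frame(province = "X", stratum = "urban", cases = 0)
  r0 <- data.frame(province = "X", stratum = "urban", cases = 5)
  tx <- difference_table(h0, r0)
  expect_true(all(is.na(tx$diff_pct)))
})

test_that("footer identity holds on randomized tables", {
  for (s in 1:5) {
    set.seed(s)
    hrp <- expand.grid(province = paste0("p", 1:6),
                       stratum = c("urban", "rural"),
                       stringsAsFactors = FALSE)
    hrp$cases <- rpois(12, 300)
    rp <- hrp
    rp$cases <- hrp$cases + sample(-50:50, 12, TRUE)
    tab <- difference_table(hrp, rp)
    foot <- attr(tab, "footer")
    for (i in seq_len(nrow(foot))) {
      d <- tab$diff[tab$stratum == foot$stratum[i]]
      expect_equal(foot$net[i], sum(d))
      expect_equal(foot$absolute_discrepancy[i], sum(abs(d)))
    }
  }
})

test_that("indirect standardization matches hand computations", {
  # two bands, equal populations, double the standard risk
  res <- indirect_asir(220, c(1e5, 1e5),
                       c(`a` = 10, `b` = 100), c(`a` = 0.5, `b` = 0.5))
  expect_equal(res$expected, 110)
  expect_equal(res$sir, 2)
  expect_equal(res$asir, 2 * 55)

  # local rates equal to the standard: SIR 1, ASIR = standard crude rate
  sched <- c(`a` = 20, `b` = 80)
  w <- c(`a` = 0.7, `b` = 0.3)
  n <- c(5e4, 2e5)
  obs <- sum(n * sched / 1e5)
  res2 <- indirect_asir(obs, n, sched, w)
  expect_equal(res2$sir, 1)
  expect_equal(res2$asir, sum(w * sched))

  expect_equal(indirect_asir(0, n, sched, w)$asir, 0)
  # scaling populations scales expected, leaves proportional SIR unchanged
  res3 <- indirect_asir(obs * 3, n * 3, sched, w)
  expect_equal(res3$expected, res2$expected * 3)
  expect_equal(res3$sir, res2$sir)
  expect_error(indirect_asir(1, n, sched, c(0.5, 0.6)), "sum to 1")
})

test_that("province schedules scale the national schedule proportionally", {
  nat <- c(`50-54` = 10, `55-59` = 40)
  pc <- data.frame(province = c("A", "B"), crude = c(5, 20))
  ps <- province_age_schedules(nat, pc, national_crude = 10)
  expect_equal(ps$rate[ps$province == "A"], c(5, 20))
  expect_equal(ps$rate[ps$province == "B"], c(20, 80))
})
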