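test_that("wilson_ci agrees with prop.test(correct = FALSE) oracle", {
  set.seed(3)
  for (i in 1:30) {
    P <- sample(50:1e6, 1)
    n <- rbinom(1, P, runif(1, 0, 0.2))
    got <- wilson_ci(n, P)
    want <- 1000 * prop.test(n, P, correct = FALSE)$conf.int
    expect_equal(unname(got), as.numeric(want), tolerance = 1e-10)
    ## interval inside [0, 1000] and contains the point estimate
    expect_true(got[1] >= 0 && got[2] <= 1000)
    expect_true(got[1] <= 1000 * n / P && 1000 * n / P <= got[2])
  }
  expect_equal(unname(wilson_ci(0, 100)[1]), 0)
  expect_error(wilson_ci(1, 0), "P = 0")
})

test_that("crude_rate computes 1000*n/P with Wilson CI", {
  r <- crude_rate(0, 1000)
  expect_equal(r$rate, 0)
  r <- crude_rate(12379, 938664)
  expect_equal(round(r$rate, 2), 13.19)
  expect_error(crude_rate(5, 0), "P = 0")
  expect_error(crude_rate(10, 5))
})

test_that("crude rate equals population-weighted mean of class rates", {
  sim <- small_sim(n = 6000)
  co <- identify_cohort(sim$db, codebook(), 2021)
  strat <- stratified_counts(co, sim$registry, "dementia")
  agg <- strat[, .(n = sum(cases), P = sum(P)), by = age_class]
  crude <- 1000 * sum(agg$n) / sum(agg$P)
  weighted <- sum((agg$P / sum(agg$P)) * 1000 * agg$n / agg$P)
  expect_equal(crude, weighted, tolerance = 1e-12)
  ## and stratum invariants hold
  expect_true(all(strat$cases <= strat$P))
  expect_true(all(strat[, c(cases, new_cases, deaths)] >= 0))
})

test_that("direct standardization: dot product, identity, errors", {
  ## two classes, rates 10 and 20 per 1,000, equal weights -> 15
  strat <- data.table(age_class = c("40-44", "45-49"),
                      n = c(10L, 20L), P = c(1000L, 1000L))
  std <- data.table(age_class = c("40-44", "45-49"), weight = c(0.5, 0.5))
  expect_equal(age_adjusted_rate(strat, std)$rate, 15)

  ## weights proportional to P -> adjusted equals crude (identity)
  set.seed(8)
  P <- sample(1000:5000, 13)
  n <- rbinom(13, P, seq(0.005, 0.2, length.out = 13))
  strat <- data.table(age_class = age_classes()$age_class, n = n, P = P)
  std <- data.table(age_class = strat$age_class, weight = P / sum(P))
  expect_equal(age_adjusted_rate(strat, std)$rate,
               1000 * sum(n) / sum(P), tolerance = 1e-12)

  ## 13-class fixture against an independent dot-product recomputation
  who <- std_population("WHO_2000_2025", 40)
  got <- age_adjusted_rate(strat, who)$rate
  w <- setNames(who$weight, as.character(who$age_class))
  want <- 0
  for (i in seq_len(nrow(strat)))  # spreadsheet-style loop oracle
    want <- want + w[[as.character(strat$age_class[i])]] *
      1000 * strat$n[i] / strat$P[i]
  expect_equal(got, want, tolerance = 1e-12)

  ## empty stratum with positive weight errors, naming the class
  bad <- copy(strat)[age_class == "90-94", P := 0L]
  expect_error(age_adjusted_rate(bad, who), "90-94")
})

test_that("standard populations are renormalized over the age range", {
  for (nm in c("WHO_2000_2025", "EUROSTAT_ESP")) {
    for (m in c(40L, 65L)) {
      s <- std_population(nm, m)
      expect_equal(sum(s$weight), 1)
      expect_equal(nrow(s), sum(age_classes()$lower >= m))
    }
  }
  ## WHO is bottom-heavier than ESP over 40+: its 40-44 share is larger
  who <- std_population("WHO_2000_2025", 40)
  esp <- std_population("EUROSTAT_ESP", 40)
  expect_gt(who$weight[1], esp$weight[1])
})

test_that("bootstrap interval: determinism, degenerate cases, convergence", {
  std <- std_population("WHO_2000_2025", 40)
  set.seed(10)
  sc <- age_classes()$age_class
  tab <- data.table(age_class = sample(sc, 5000, replace = TRUE),
                    case = runif(5000) < 0.05)
  ci1 <- bootstrap_ci_adjusted(tab, std, B = 500, seed = 123)
  ci2 <- bootstrap_ci_adjusted(tab, std, B = 500, seed = 123)
  expect_identical(ci1, ci2)
  ## all-case table -> (1000, 1000); no-case -> (0, 0) with warning
  allc <- copy(tab)[, case := TRUE]
  expect_equal(unname(bootstrap_ci_adjusted(allc, std, B = 100, seed = 1)),
               c(1000, 1000))
  none <- copy(tab)[, case := FALSE]
  expect_warning(ci0 <- bootstrap_ci_adjusted(none, std, B = 100),
                 "degenerate")
  expect_equal(unname(ci0), c(0, 0))
  expect_error(bootstrap_ci_adjusted(tab, std, B = 50), "B must be")
  ## width stabilizes: B=2000 vs B=5000 widths differ < 2%
  w2 <- diff(bootstrap_ci_adjusted(tab, std, B = 2000, seed = 5))
  w5 <- diff(bootstrap_ci_adjusted(tab, std, B = 5000, seed = 5))
  expect_lt(abs(w5 - w2) / w5, 0.02)
})

test_that("irr and irr_ci follow the Poisson log-normal form", {
  expect_equal(round(irr(2.43, 3.16), 2), 0.77)
  expect_equal(irr(4, 4), 1)
  expect_error(irr(1, 0), "baseline")

  e <- irr_ci(100, 1e5, 100, 1e5)
  expect_equal(e$irr, 1)
  ## closed-form oracle exp(+/- 1.96 * sqrt(0.02))
  z <- qnorm(0.975)
  expect_equal(e$ci_low, exp(-z * sqrt(0.02)), tolerance = 1e-12)
  expect_equal(e$ci_high, exp(z * sqrt(0.02)), tolerance = 1e-12)
  expect_equal(round(c(e$ci_low, e$ci_high), 2), c(0.76, 1.32))
  expect_equal(irr_ci(50, 1e5, 200, 1e5)$irr, 0.25)
  ## CI width shrinks with counts at fixed IRR
  wide <- irr_ci(20, 1e4, 20, 1e4)
  narrow <- irr_ci(2000, 1e6, 2000, 1e6)
  expect_lt(narrow$ci_high - narrow$ci_low, wide$ci_high - wide$ci_low)
  expect_error(irr_ci(0, 10, 5, 10), "> 0")
})

test_that("mortality uses the total resident population as denominator", {
  ## one group member dies among a large population: rate reflects P, not
  ## the case count
  reg <- mk_registry(sprintf("N%03d", 1:200))
  reg[person_id == "N001", death_date := d("2021-08-01")]
  rx <- rbind(mk_rx("N001", c("2021-01-10", "2021-02-10")),
              mk_rx("N002", c("2020-01-10", "2020-02-10")))
  co <- identify_cohort(mk_db(reg, rx), codebook(), 2021)
  tab <- rate_table(co, reg, "parkinsonism")
  crude <- tab[age_class == "Crude"]
  expect_equal(crude$deaths, 1L)
  expect_equal(crude$mortality, 1000 * 1 / 199)  # 199 alive on Dec 31
})

test_that("rate_table: structure, over-65 restriction, zero mortality", {
  sim <- small_sim(n = 6000)
  co <- identify_cohort(sim$db, codebook(), 2021)
  tab <- rate_table(co, sim$registry, "parkinsonism")
  expect_equal(nrow(tab), 19L)  # 13 classes + 6 summary rows
  s65 <- tab[age_class == "Crude (over 65)"]
  cls65 <- tab[age_class %in% age_classes()[lower >= 65, age_class]]
  expect_equal(s65$cases, sum(cls65$cases))
  expect_equal(s65$P, sum(cls65$P))
  ## per-sex tables partition the totals
  m <- rate_table(co, sim$registry, "parkinsonism", sex = "male")
  f <- rate_table(co, sim$registry, "parkinsonism", sex = "female")
  expect_equal(m[age_class == "Crude", cases] +
                 f[age_class == "Crude", cases],
               tab[age_class == "Crude", cases])
  ## no deaths -> mortality column identically zero
  reg <- mk_registry(sprintf("Z%02d", 1:50))
  rx <- mk_rx("Z01", c("2021-01-10", "2021-02-10"))
  co0 <- identify_cohort(mk_db(reg, rx), codebook(), 2021)
  tab0 <- suppressMessages(rate_table(co0, reg, "parkinsonism"))
  expect_true(all(tab0$deaths == 0))
  ## populated rows show 0.00 mortality; unpopulated classes are blank
  expect_true(all(tab0[P > 0, mortality] == 0))
  expect_true(all(is.na(tab0[P == 0, mortality])))
})
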