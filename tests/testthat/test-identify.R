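cb <- codebook()
eoy <- d("2021-12-31")

hist_of <- function(rx = empty_rx(), hdr = empty_hdr(), ex = empty_ex(),
                    id = "A") {
  person_history(mk_db(mk_registry(id), rx, hdr, ex), id)
}

test_that("repeated-prescription rule matches brute-force oracle", {
  ## forced examples
  expect_true(qualifies_repeated(mk_rx("A", c("2021-01-01", "2021-01-31")),
                                 "N04BA", cb)$qualifies)
  expect_false(qualifies_repeated(mk_rx("A", "2021-01-01"),
                                  "N04BA", cb)$qualifies)
  expect_false(qualifies_repeated(
    mk_rx("A", c("2020-01-01", "2021-02-15")), "N04BA", cb)$qualifies)
  ## qualifying date is the start of the earliest qualifying span
  q <- qualifies_repeated(
    mk_rx("A", c("2016-01-01", "2018-03-01", "2018-06-01")), "N04BA", cb)
  expect_equal(q$first_date, d("2018-03-01"))

  ## property: random date sets vs combinatorial oracle
  set.seed(42)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    w <- sample(c(90L, 365L), 1)
    cbi <- codebook(repeat_min_count = k, repeat_window_days = w)
    dates <- d("2016-01-01") + sample.int(2000L, sample(1:8, 1))
    got <- qualifies_repeated(mk_rx("A", dates), "N04BA", cbi)
    want <- oracle_repeated(dates, k, w)
    expect_equal(got$qualifies, want$qualifies)
    if (want$qualifies) expect_equal(got$first_date, want$first_date)
  }
  ## non-matching ATC never qualifies
  expect_false(qualifies_repeated(
    mk_rx("A", c("2021-01-01", "2021-01-02"), atc = "C09AA02"),
    "N04BA", cb)$qualifies)
})

test_that("parkinsonism classification: prescriptions or exemption 038", {
  r <- classify_parkinsonism(hist_of(ex = mk_ex("A", "2019-04-01", "038")),
                             cb, eoy)
  expect_true(r$case)
  expect_equal(r$criteria, "park_exemption")
  expect_equal(r$first_date, d("2019-04-01"))

  r <- classify_parkinsonism(
    hist_of(rx = mk_rx("A", c("2020-02-01", "2020-05-01"), "N04BC05")),
    cb, eoy)
  expect_true(r$case)
  expect_equal(r$criteria, "park_rx")
  expect_equal(r$sources, "prescription")

  ## single prescription + unrelated exemption: not a case
  r <- classify_parkinsonism(
    hist_of(rx = mk_rx("A", "2020-02-01"),
            ex = mk_ex("A", "2020-01-01", "048")), cb, eoy)
  expect_false(r$case)

  ## events after as_of are ignored
  r <- classify_parkinsonism(
    hist_of(rx = mk_rx("A", c("2022-02-01", "2022-03-01"))), cb, eoy)
  expect_false(r$case)
})

test_that("dementia truth table: core criteria, proxy, psychiatric veto", {
  ## enumerate all subsets of {dem_rx, dem_hdr, dem_exemption, dem_proxy}
  ## x psychiatric label; expected rule: case iff any core criterion, or
  ## proxy without psych labels
  for (mask in 0:15) {
    has <- as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L)
    for (psych in c(FALSE, TRUE)) {
      rx <- rbind(
        if (has[1]) mk_rx("A", c("2020-01-10", "2020-02-10"), "N06DA02"),
        if (has[4]) mk_rx("A", c("2020-03-01", "2020-04-01"), "N05AH04"))
      hdr <- if (has[2]) mk_hdr("A", "2020-05-01", dx1 = "2941") else NULL
      ex <- rbind(if (has[3]) mk_ex("A", "2020-06-01", "011"),
                  if (psych) mk_ex("A", "2018-01-01", "044"))
      h <- hist_of(rx = if (is.null(rx)) empty_rx() else rx,
                   hdr = if (is.null(hdr)) empty_hdr() else hdr,
                   ex = if (is.null(ex)) empty_ex() else ex)
      r <- classify_dementia(h, cb, eoy)
      core <- any(has[1:3])
      expect_equal(r$case, core || (has[4] && !psych),
                   info = sprintf("mask=%d psych=%s", mask, psych))
      expect_equal(r$excluded_psychiatric, !core && has[4] && psych,
                   info = sprintf("mask=%d psych=%s", mask, psych))
    }
  }
})

test_that("proxy criterion details: trazodone counts, psych discharge vetoes", {
  ## repeated trazodone, clean history -> case via proxy
  r <- classify_dementia(
    hist_of(rx = mk_rx("A", c("2021-01-05", "2021-03-05"), "N06AX05")),
    cb, eoy)
  expect_true(r$case)
  expect_equal(r$criteria, "dem_proxy")
  ## psych discharge (any dx slot) vetoes proxy-only
  r <- classify_dementia(
    hist_of(rx = mk_rx("A", c("2021-01-05", "2021-03-05"), "N05AH04"),
            hdr = mk_hdr("A", "2017-01-01",
                         dx = c("4019", "2962"))), cb, eoy)
  expect_false(r$case)
  expect_true(r$excluded_psychiatric)
  ## dementia ICD-9 in any of the six positions overrides the veto
  r <- classify_dementia(
    hist_of(rx = mk_rx("A", c("2021-01-05", "2021-03-05"), "N05AH04"),
            hdr = rbind(mk_hdr("A", "2017-01-01", dx = c("4019", "2962")),
                        mk_hdr("A", "2019-01-01",
                               dx = c("4019", "250", "33182")))), cb, eoy)
  expect_true(r$case)
  expect_true("dem_hdr" %in% r$criteria)
  expect_false(r$excluded_psychiatric)
})

test_that("assign_group maps the four flag combinations", {
  expect_equal(assign_group(c(TRUE, FALSE, TRUE, FALSE),
                            c(TRUE, TRUE, FALSE, FALSE)),
               c("both", "dementia", "parkinsonism", "none"))
})

test_that("is_incident applies the disease-free look-back", {
  ## first-ever tracer events in 2021, empty before -> incident
  h <- hist_of(rx = mk_rx("A", c("2021-02-01", "2021-04-01")))
  expect_true(is_incident(h, cb, 2021))
  ## tracer exemption in 2018 + new prescriptions 2021 -> not incident
  h <- hist_of(rx = mk_rx("A", c("2021-02-01", "2021-04-01")),
               ex = mk_ex("A", "2018-06-01", "038"))
  expect_false(is_incident(h, cb, 2021))
  ## a SINGLE prior matching prescription disqualifies too
  h <- hist_of(rx = mk_rx("A", c("2019-06-01", "2021-02-01", "2021-04-01")))
  expect_false(is_incident(h, cb, 2021))
  ## proxy prescriptions count as look-back evidence
  h <- hist_of(rx = rbind(mk_rx("A", c("2021-02-01", "2021-04-01")),
                          mk_rx("A", "2020-03-01", "N05AH04")))
  expect_false(is_incident(h, cb, 2021))
  ## evidence before the window does not disqualify (truncated look-back):
  ## reference 2017 with lookback 1 ignores a 2015 record
  h <- hist_of(rx = rbind(mk_rx("A", "2015-03-01"),
                          mk_rx("A", c("2017-02-01", "2017-04-01"))))
  expect_true(is_incident(h, cb, 2017, lookback_years = 1L))
  expect_false(is_incident(h, cb, 2017, lookback_years = 5L))
  ## contract: no qualifying evidence in the year
  expect_error(is_incident(hist_of(rx = mk_rx("A", "2019-01-01")), cb, 2021),
               "contract")
})

test_that("identify_cohort: groups, set identity, membership, determinism", {
  ## hand-built mixed cohort
  reg <- mk_registry(c("P1", "P2", "P3", "P4", "P5", "P6"))
  reg[person_id == "P4", death_date := d("2021-06-15")]   # dies in ref year
  reg[person_id == "P5", residency_end := d("2020-12-31")] # moved away
  rx <- rbind(
    mk_rx("P1", c("2020-01-01", "2020-03-01")),                # park
    mk_rx("P2", c("2019-05-01", "2019-07-01"), "N06DA02"),     # dementia
    mk_rx("P3", c("2018-02-01", "2018-04-01")),                # both:
    mk_rx("P3", c("2021-02-01", "2021-04-01"), "N06AX11"),     #  +proxy
    mk_rx("P4", c("2021-01-10", "2021-02-10")),                # dies
    mk_rx("P5", c("2020-01-01", "2020-03-01")))                # non-resident
  co <- identify_cohort(mk_db(reg, rx), cb, 2021)
  expect_setequal(co$cases$person_id, c("P1", "P2", "P3"))
  expect_equal(co$cases[person_id == "P3", group], "both")
  ## both-group = parkinsonism-set intersect dementia-set
  expect_equal(co$cases[group == "both", person_id],
               intersect(
                 co$cases[group %in% c("parkinsonism", "both"), person_id],
                 co$cases[group %in% c("dementia", "both"), person_id]))
  ## the in-year death is reported for mortality, not prevalence
  expect_equal(co$deaths$person_id, "P4")
  ## stage ledger monotone
  expect_true(co$counts["prevalent"] <= co$counts["classified"])
  expect_true(co$counts["incident"] <= co$counts["prevalent"])

  ## determinism under input order shuffling
  set.seed(1)
  co2 <- identify_cohort(mk_db(reg[sample(.N)], rx[sample(.N)]), cb, 2021)
  expect_equal(data.table::setorder(copy(co$cases), person_id),
               data.table::setorder(copy(co2$cases), person_id))
})

test_that("monotone properties: psych labels and dementia discharges", {
  set.seed(99)
  ## adding a psychiatric exemption never creates a dementia case, and
  ## removes one only when proxy was the sole criterion
  for (i in 1:20) {
    rx <- rbind(
      if (runif(1) < 0.5) mk_rx("A", d("2020-01-01") + sample.int(300, 2),
                                "N06DA02"),
      if (runif(1) < 0.7) mk_rx("A", d("2020-01-01") + sample.int(300, 2),
                                "N05AH04"))
    if (is.null(rx)) rx <- empty_rx()
    hdr <- if (runif(1) < 0.3) mk_hdr("A", "2019-05-01") else empty_hdr()
    base <- classify_dementia(hist_of(rx = rx, hdr = hdr), cb, eoy)
    lab <- classify_dementia(hist_of(rx = rx, hdr = hdr,
                                     ex = mk_ex("A", "2017-01-01", "044")),
                             cb, eoy)
    expect_true(!lab$case | base$case)        # never creates
    if (base$case && !lab$case)
      expect_equal(base$criteria, "dem_proxy") # removes only proxy-only
    ## adding a dementia discharge never removes a case
    plus <- classify_dementia(
      hist_of(rx = rx, hdr = rbind(hdr, mk_hdr("A", "2021-06-01")),
              ex = mk_ex("A", "2017-01-01", "044")), cb, eoy)
    expect_true(plus$case >= lab$case)
  }
})

test_that("source and drug breakdowns tabulate contributing evidence", {
  reg <- mk_registry(c("E1", "E2", "R1"))
  ex <- rbind(mk_ex("E1", "2019-01-01", "038"),
              mk_ex("E2", "2020-01-01", "038"))
  rx <- mk_rx("R1", c("2020-01-01", "2020-02-01"), "N04BC05")
  co <- identify_cohort(mk_db(reg, rx, ex = ex), cb, 2021)
  sb <- co$source_breakdown
  expect_equal(sb[group == "parkinsonism" & source == "exemption", cases], 2L)
  expect_equal(sb[group == "parkinsonism" & source == "prescription", cases],
               1L)
  db <- co$drug_breakdown
  expect_equal(db[disease == "parkinsonism", sum(n)], 1L)
  expect_equal(db[subgroup == "dopamine agonists (N04BC)", share], 1)
})
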