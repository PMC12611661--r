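## Crude, age-specific and directly standardized rates with Wilson and
## bootstrap confidence intervals; Poisson incidence rate ratios.
## Convention: all rates are per 1,000 and displayed to 2 decimals
## (half-up); internal values are never rounded.

#' 5-year age class scheme from age 40
#'
#' The 13 contiguous classes 40-44, 45-49, ..., 95-99, 100+ used for all
#' stratified estimates.
#'
#' @return data.table with `age_class` (ordered factor levels), `lower`,
#'   `upper` (Inf for the open top class).
#' @export
age_classes <- function() {
  lower <- c(seq(40L, 95L, by = 5L), 100L)
  upper <- c(seq(44L, 99L, by = 5L), Inf)
  lab <- c(sprintf("%d-%d", head(lower, -1L), head(upper, -1L)), "100+")
  data.table(age_class = lab, lower = lower, upper = upper)
}

#' Assign ages to 5-year classes
#'
#' @param age integer vector of completed years; must be >= 40.
#' @return factor with the [age_classes()] labels.
#' @export
age_class_of <- function(age) {
  sc <- age_classes()
  if (any(age < 40, na.rm = TRUE)) stop("age below 40 outside the scheme")
  i <- findInterval(age, sc$lower)
  factor(sc$age_class[i], levels = sc$age_class)
}

#' Completed age at a reference date
#'
#' @param birth_date,as_of Date vectors.
#' @return integer completed years.
#' @export
age_at <- function(birth_date, as_of) {
  b <- as.POSIXlt(birth_date); a <- as.POSIXlt(as_of)
  age <- a$year - b$year
  age - ((a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday))
}

#' Half-up rounding
#'
#' Published rate tables round half-up; base R's `round()` is half-even.
#'
#' @param x numeric.
#' @param digits decimal places (default 2, the table convention).
#' @export
round_half_up <- function(x, digits = 2L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Wilson score confidence interval for a rate per 1,000
#'
#' Standard Wilson score interval on the proportion `n/P`, scaled to the
#' per-1,000 rate scale.  Used for crude and age-specific rates.
#'
#' @param n event count (0 <= n <= P).
#' @param P population denominator (> 0).
#' @param level confidence level, default 0.95.
#' @return numeric `c(low, high)` per 1,000.
#' @export
wilson_ci <- function(n, P, level = 0.95) {
  if (P <= 0) stop("undefined rate: P = 0")
  if (n < 0 || n > P) stop("need 0 <= n <= P")
  z <- qnorm(1 - (1 - level) / 2)
  p <- n / P
  denom <- 1 + z^2 / P
  centre <- (p + z^2 / (2 * P)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / P + z^2 / (4 * P^2))
  1000 * c(low = centre - half, high = centre + half)
}

.rate_estimate <- function(kind, scope, n, P, rate, ci, ci_method,
                           standard = NA_character_) {
  structure(list(kind = kind, scope = scope, n = n, P = P, rate = rate,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 ci_method = ci_method, standard = standard),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s %s rate%s: %.2f per 1,000 (95%% CI %.2f-%.2f, %s)\n",
              x$scope, x$kind,
              if (!is.na(x$standard)) paste0(" [", x$standard, "]") else "",
              round_half_up(x$rate), round_half_up(x$ci_low),
              round_half_up(x$ci_high), x$ci_method))
  if (!is.na(x$n)) cat(sprintf("  n = %s / P = %s\n",
                               format(x$n, big.mark = ","),
                               format(x$P, big.mark = ",")))
  invisible(x)
}

#' Crude rate per 1,000 with Wilson interval
#'
#' `r = 1000 * n / P`: cases (or new cases, or deaths) over the total
#' resident population of the same year.  Mortality uses the same total
#' population denominator, not the case count.
#'
#' @param n event count.
#' @param P population (> 0).
#' @param kind one of `"prevalence"`, `"incidence"`, `"mortality"`.
#' @param level confidence level for the Wilson interval.
#' @return a `rate_estimate`.
#' @examples
#' crude_rate(12379, 938664)  # 13.19 per 1,000 (12.96-13.42)
#' @export
crude_rate <- function(n, P, kind = c("prevalence", "incidence",
                                      "mortality"), level = 0.95) {
  kind <- match.arg(kind)
  if (P <= 0) stop("undefined rate: P = 0")
  if (n < 0 || n > P) stop("need 0 <= n <= P")
  .rate_estimate(kind, "crude", n, P, 1000 * n / P,
                 wilson_ci(n, P, level), "wilson")
}

#' Standard populations for direct age standardization
#'
#' Loads the WHO world standard population 2000-2025 or the Eurostat
#' European Standard Population 2013, restricted to an analysis age range
#' and renormalized so the included class weights sum to 1.  The shipped
#' weights are the published 5-year shares; ESP 2013 defines an open 95+
#' class whose weight is split 90/10 between 95-99 and 100+ to fit the
#' 13-class scheme (documented, editable in the CSV).
#'
#' @param name `"WHO_2000_2025"` or `"EUROSTAT_ESP"`.
#' @param min_age lower bound of the analysis range (40 for the full cohort,
#'   65 for the restricted estimates).
#' @return object of class `std_pop`: data.table `age_class`, `weight`
#'   (summing to 1), with attributes `name` and `renormalized`.
#' @export
std_population <- function(name = c("WHO_2000_2025", "EUROSTAT_ESP"),
                           min_age = 40L) {
  name <- match.arg(name)
  file <- c(WHO_2000_2025 = "who_std.csv", EUROSTAT_ESP = "esp_std.csv")[name]
  path <- system.file("extdata", file, package = "ndtrace", mustWork = TRUE)
  w <- data.table::fread(path)
  sc <- age_classes()[lower >= min_age]
  w <- w[age_class %in% sc$age_class]
  if (nrow(w) != nrow(sc))
    stop("standard population missing classes: ",
         paste(setdiff(sc$age_class, w$age_class), collapse = ", "))
  w[, weight := weight / sum(weight)]
  w[, age_class := factor(age_class, levels = age_classes()$age_class)]
  data.table::setorder(w, age_class)
  data.table::setattr(w, "name", name)
  data.table::setattr(w, "renormalized", TRUE)
  data.table::setattr(w, "class", c("std_pop", class(w)))
  w[]
}

#' Directly age-standardized rate
#'
#' `r = 1000 * sum_g (n_g / P_g) * w_g` over the classes of the standard,
#' with weights renormalized over the analysis age range.
#'
#' @param strat data.frame with `age_class`, `n` (events) and `P`
#'   (population) per class; every class with positive weight must have
#'   `P > 0`.
#' @param std a [std_population()] (or any data.frame with `age_class`,
#'   `weight` summing to 1).
#' @param kind rate kind label.
#' @return a `rate_estimate` with `scope = "adjusted"` and no CI (see
#'   [bootstrap_ci_adjusted()] for the interval).
#' @export
age_adjusted_rate <- function(strat, std,
                              kind = c("prevalence", "incidence",
                                       "mortality")) {
  kind <- match.arg(kind)
  strat <- as.data.table(strat)
  std <- as.data.table(std)
  m <- std[strat, on = "age_class"]
  miss <- std[!std$age_class %in% strat$age_class & weight > 0]
  if (nrow(miss))
    stop("no stratum data for positive-weight class(es): ",
         paste(miss$age_class, collapse = ", "))
  bad <- m[weight > 0 & (is.na(P) | P <= 0)]
  if (nrow(bad))
    stop("empty stratum with positive weight: ",
         paste(bad$age_class, collapse = ", "))
  m <- m[weight > 0]
  rate <- 1000 * m[, sum(weight * n / P)]
  .rate_estimate(kind, "adjusted", sum(strat$n), sum(strat$P), rate,
                 c(NA_real_, NA_real_), "none",
                 standard = attr(std, "name") %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bootstrap percentile interval for the age-adjusted rate
#'
#' Resamples persons with replacement from the region and recomputes the
#' standardized rate on each resample (percentile interval).  Because the
#' person-level table carries only the age class and a binary case flag,
#' resampling n persons is equivalent to a multinomial redraw of the
#' (age class x case) contingency cells, which is how it is computed; the
#' interval is identical in distribution to row-level resampling but runs
#' in O(B x classes).  A class with zero resampled population contributes a
#' zero rate to that replicate.
#'
#' @param person_table data.frame with one row per person: `age_class` and
#'   logical `case`.
#' @param std a [std_population()].
#' @param B number of resamples (>= 100; 5,000 for production estimates).
#' @param level confidence level.
#' @param seed optional integer for reproducibility.
#' @return numeric `c(low, high)` per 1,000.
#' @export
bootstrap_ci_adjusted <- function(person_table, std, B = 5000L,
                                  level = 0.95, seed = NULL) {
  if (B < 100L) stop("B must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  pt <- as.data.table(person_table)
  stopifnot(all(c("age_class", "case") %in% names(pt)))
  std <- as.data.table(std)
  n_tot <- nrow(pt)
  if (n_tot == 0L) stop("empty person table")
  if (!any(pt$case)) {
    warning("degenerate table: no cases anywhere; interval (0, 0)")
    return(c(low = 0, high = 0))
  }
  pt[, age_class := factor(as.character(age_class),
                           levels = levels(factor(std$age_class)))]
  cells <- pt[, .N, by = .(age_class, case)]
  counts <- cells$N
  cls <- as.character(cells$age_class)
  is_case <- cells$case
  w <- setNames(std$weight, as.character(std$age_class))
  draws <- rmultinom(B, n_tot, counts / n_tot)  # cells x B
  classes <- sort(unique(cls))
  num <- matrix(0, length(classes), B,
                dimnames = list(classes, NULL))
  den <- matrix(0, length(classes), B,
                dimnames = list(classes, NULL))
  for (i in seq_along(counts)) {
    den[cls[i], ] <- den[cls[i], ] + draws[i, ]
    if (is_case[i]) num[cls[i], ] <- num[cls[i], ] + draws[i, ]
  }
  frac <- num / den
  frac[den == 0] <- 0
  rates <- 1000 * colSums(frac * w[classes])
  a <- (1 - level) / 2
  q <- quantile(rates, c(a, 1 - a), names = FALSE)
  c(low = q[1], high = q[2])
}

#' Incidence rate ratio between two crude rates
#'
#' @param rate_2 rate of the comparison year (per 1,000).
#' @param rate_1 rate of the baseline year (per 1,000); must be > 0.
#' @return the ratio `rate_2 / rate_1`.
#' @examples
#' irr(2.43, 3.16)  # 0.77: the 2020-vs-2019 style year-on-year drop
#' @export
irr <- function(rate_2, rate_1) {
  if (rate_1 <= 0) stop("baseline rate must be > 0")
  rate_2 / rate_1
}

#' Incidence rate ratio with Poisson log-normal confidence interval
#'
#' `IRR = (c2/P2) / (c1/P1)` with
#' `CI = exp(log(IRR) +/- z * sqrt(1/c2 + 1/c1))`, assuming Poisson counts.
#'
#' @param cases_2,pop_2 comparison-year count and population.
#' @param cases_1,pop_1 baseline-year count and population.
#' @param level confidence level.
#' @return object of class `irr_estimate`: list with `irr`, `ci_low`,
#'   `ci_high`, `rate_num`, `rate_den`, case counts.
#' @export
irr_ci <- function(cases_2, pop_2, cases_1, pop_1, level = 0.95) {
  if (any(c(cases_2, pop_2, cases_1, pop_1) <= 0))
    stop("all counts must be > 0 (no continuity correction by design)")
  r2 <- 1000 * cases_2 / pop_2
  r1 <- 1000 * cases_1 / pop_1
  est <- r2 / r1
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / cases_2 + 1 / cases_1)
  structure(list(irr = est,
                 ci_low = exp(log(est) - z * se),
                 ci_high = exp(log(est) + z * se),
                 rate_num = r2, rate_den = r1,
                 cases_2 = cases_2, cases_1 = cases_1),
            class = "irr_estimate")
}

#' @export
print.irr_estimate <- function(x, ...) {
  cat(sprintf("IRR %.2f (95%% CI %.2f-%.2f); rates %.2f vs %.2f per 1,000\n",
              round_half_up(x$irr), round_half_up(x$ci_low),
              round_half_up(x$ci_high), round_half_up(x$rate_num),
              round_half_up(x$rate_den)))
  invisible(x)
}

## ---- stratified counts and the full results table -------------------------

#' Stratified counts for a reference year
#'
#' Per (age class, sex): resident population on Dec 31, prevalent cases,
#' new (incident) cases and deaths for one disease group.
#'
#' @param cohort a `case_cohort` from [identify_cohort()].
#' @param registry registry table (all persons, for denominators).
#' @param group `"parkinsonism"`, `"dementia"` or `"both"`; group
#'   membership is inclusive for the component diseases, i.e.
#'   `"parkinsonism"` counts persons with parkinsonism with or without
#'   dementia, matching how the three analysis groups are tabulated.
#' @param inclusive if FALSE, use the exclusive group label instead.
#' @return data.table: `age_class`, `sex`, `P`, `cases`, `new_cases`,
#'   `deaths`.
#' @export
stratified_counts <- function(cohort, registry, group, inclusive = TRUE) {
  stopifnot(inherits(cohort, "case_cohort"))
  reg <- as.data.table(registry)
  as_of <- as.Date(sprintf("%d-12-31", cohort$reference_year))
  reg <- reg[(is.na(death_date) | death_date >= as_of) &
               (is.na(residency_start) | residency_start <= as_of) &
               (is.na(residency_end) | residency_end >= as_of)]
  reg[, age := age_at(birth_date, as_of)]
  reg <- reg[age >= 40]
  reg[, age_class := age_class_of(age)]

  g <- group
  sel <- function(tab) {
    if (!nrow(tab)) return(tab)
    if (inclusive && g != "both") tab[group == g | group == "both"]
    else tab[group == g]
  }
  grp_cases <- sel(cohort$cases)
  grp_deaths <- sel(cohort$deaths)

  grid <- data.table::CJ(age_class = age_classes()$age_class,
                         sex = c("male", "female"))
  pop <- reg[, .(P = .N), by = .(age_class, sex)]
  pop[, age_class := as.character(age_class)]
  pop <- pop[grid, on = c("age_class", "sex")]
  pop[is.na(P), P := 0L]
  add <- function(base, ids, col) {
    x <- reg[person_id %in% ids, .(n = .N), by = .(age_class, sex)]
    data.table::setnames(x, "n", col)
    x[base, on = c("age_class", "sex")]
  }
  out <- add(pop, grp_cases$person_id, "cases")
  out <- add(out, grp_cases[incident == TRUE, person_id], "new_cases")
  ## deaths: people who died in-year are no longer in the Dec-31 registry
  ## slice; stratify them by age at death year end from the full registry
  regd <- as.data.table(registry)
  regd <- regd[person_id %in% grp_deaths$person_id]
  if (nrow(regd)) {
    regd[, age := age_at(birth_date, as_of)]
    regd <- regd[age >= 40]
    regd[, age_class := age_class_of(age)]
    d <- regd[, .(deaths = .N), by = .(age_class, sex)]
    out <- d[out, on = c("age_class", "sex")]
  } else out[, deaths := 0L]
  for (cn in c("cases", "new_cases", "deaths"))
    out[is.na(get(cn)), (cn) := 0L]
  out[, age_class := factor(age_class, levels = age_classes()$age_class)]
  data.table::setorder(out, age_class, sex)
  data.table::setcolorder(out, c("age_class", "sex", "P", "cases",
                                 "new_cases", "deaths"))
  out[]
}

#' Full rate table for one disease group
#'
#' Reproduces the canonical results-table layout: one row per 5-year age
#' class with cases / prevalence / new cases / incidence / deaths /
#' mortality (Wilson CIs), then crude, WHO- and Eurostat-adjusted rows, and
#' the same three restricted to ages 65+.  Adjusted-row CIs use the
#' person-level bootstrap when `boot_B > 0`.
#'
#' @param cohort a `case_cohort`.
#' @param registry the registry table.
#' @param group disease group (see [stratified_counts()]).
#' @param sex optional `"male"`/`"female"` restriction.
#' @param boot_B bootstrap resamples for adjusted CIs (0 = skip; 5,000 for
#'   production use).
#' @param seed seed for the bootstrap.
#' @param level confidence level.
#' @return data.table, one row per age class / summary row, with rate and
#'   CI columns per 1,000 (unrounded; use [format_rate_table()] for
#'   display).
#' @export
rate_table <- function(cohort, registry, group, sex = NULL, boot_B = 0L,
                       seed = NULL, level = 0.95) {
  strat <- stratified_counts(cohort, registry, group)
  if (!is.null(sex)) {
    sx <- sex
    strat <- strat[sex == sx]
  }
  strat <- strat[, .(P = sum(P), cases = sum(cases),
                     new_cases = sum(new_cases), deaths = sum(deaths)),
                 by = age_class]

  row_of <- function(label, n, nn, nd, P) {
    pr <- if (P > 0) wilson_ci(n, P, level) else c(NA, NA)
    ic <- if (P > 0) wilson_ci(nn, P, level) else c(NA, NA)
    mo <- if (P > 0) wilson_ci(nd, P, level) else c(NA, NA)
    rt <- function(x) if (P > 0) 1000 * x / P else NA_real_
    data.table(age_class = label, P = P, cases = n,
               prevalence = rt(n), prev_low = pr[1], prev_high = pr[2],
               new_cases = nn,
               incidence = rt(nn), inc_low = ic[1], inc_high = ic[2],
               deaths = nd,
               mortality = rt(nd), mort_low = mo[1],
               mort_high = mo[2])
  }
  per_class <- data.table::rbindlist(lapply(seq_len(nrow(strat)), function(i)
    row_of(as.character(strat$age_class[i]), strat$cases[i],
           strat$new_cases[i], strat$deaths[i], strat$P[i])))

  adj_row <- function(label, strat_sub, std, min_age) {
    ## empty classes (no residents) cannot carry standard weight: drop and
    ## renormalize, as is usual when the oldest open classes are unpopulated
    have <- strat_sub[P > 0, as.character(age_class)]
    std <- as.data.table(std)
    if (!all(as.character(std$age_class) %in% have)) {
      message(label, ": renormalizing standard over populated classes (",
              paste(setdiff(as.character(std$age_class), have),
                    collapse = ", "), " empty)")
      nm <- attr(std, "name")
      std <- std[as.character(age_class) %in% have]
      std[, weight := weight / sum(weight)]
      data.table::setattr(std, "name", nm)
    }
    mk <- function(col, kind) {
      s <- strat_sub[P > 0, .(age_class, n = get(col), P)]
      age_adjusted_rate(s, std, kind)$rate
    }
    r <- data.table(age_class = label, P = strat_sub[, sum(P)],
                    cases = strat_sub[, sum(cases)],
                    prevalence = mk("cases", "prevalence"),
                    prev_low = NA_real_, prev_high = NA_real_,
                    new_cases = strat_sub[, sum(new_cases)],
                    incidence = mk("new_cases", "incidence"),
                    inc_low = NA_real_, inc_high = NA_real_,
                    deaths = strat_sub[, sum(deaths)],
                    mortality = mk("deaths", "mortality"),
                    mort_low = NA_real_, mort_high = NA_real_)
    if (boot_B > 0L) {
      for (spec in list(c("cases", "prev_low", "prev_high"),
                        c("new_cases", "inc_low", "inc_high"),
                        c("deaths", "mort_low", "mort_high"))) {
        pt <- strat_sub[, .(age_class, n = get(spec[1]), P)]
        tab <- pt[, .(age_class = rep(age_class, P),
                      case = rep(FALSE, sum(P)))]
        ## flip the first n rows of each class to cases
        tab[, idx := seq_len(.N), by = age_class]
        lim <- setNames(pt$n, as.character(pt$age_class))
        tab[, case := idx <= lim[as.character(age_class)]]
        ci <- bootstrap_ci_adjusted(tab[, .(age_class, case)], std,
                                    B = boot_B, level = level, seed = seed)
        r[[spec[2]]] <- ci[1]; r[[spec[3]]] <- ci[2]
      }
    }
    r
  }
  restrict <- function(min_age) {
    keep <- age_classes()[lower >= min_age, age_class]
    strat[age_class %in% keep]
  }
  s40 <- strat; s65 <- restrict(65L)
  out <- rbind(
    per_class,
    row_of("Crude", s40[, sum(cases)], s40[, sum(new_cases)],
           s40[, sum(deaths)], s40[, sum(P)]),
    adj_row("Age-adj (WHO)", s40, std_population("WHO_2000_2025", 40L), 40L),
    adj_row("Age-adj (Eurostat)", s40, std_population("EUROSTAT_ESP", 40L),
            40L),
    row_of("Crude (over 65)", s65[, sum(cases)], s65[, sum(new_cases)],
           s65[, sum(deaths)], s65[, sum(P)]),
    adj_row("Age-adj (over 65, WHO)", s65,
            std_population("WHO_2000_2025", 65L), 65L),
    adj_row("Age-adj (over 65, Eurostat)", s65,
            std_population("EUROSTAT_ESP", 65L), 65L))
  data.table::setattr(out, "group", group)
  data.table::setattr(out, "reference_year", cohort$reference_year)
  out[]
}

#' Format a rate table for display/export
#'
#' Rounds rates half-up to 2 decimals, per-1,000 scale, and renders CIs as
#' `rate (low-high)` strings.
#'
#' @param tab output of [rate_table()].
#' @return data.table of display strings.
#' @export
format_rate_table <- function(tab) {
  f <- function(r, lo, hi) ifelse(
    is.na(r), "",
    ifelse(is.na(lo), sprintf("%.2f", round_half_up(r)),
           sprintf("%.2f (%.2f-%.2f)", round_half_up(r),
                   round_half_up(lo), round_half_up(hi))))
  tab[, .(age_class, cases,
          prevalence = f(prevalence, prev_low, prev_high),
          new_cases,
          incidence = f(incidence, inc_low, inc_high),
          deaths,
          mortality = f(mortality, mort_low, mort_high))]
}
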