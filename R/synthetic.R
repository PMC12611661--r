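## Synthetic region generator: emulates the four linked administrative
## databases (registry, prescriptions, discharges, exemptions) with planted
## age/sex-graded disease status, tracer-prescription behaviour, proxy-drug
## confounders with psychiatric labels, deaths, and municipalities, so every
## downstream stage is testable without any real data.

## default age structure of an aging region (shares per 5-year class, 40+)
.default_structure <- function() {
  sc <- age_classes()
  data.table(
    age_class = sc$age_class,
    share = c(0.105, 0.115, 0.125, 0.120, 0.110, 0.100, 0.090, 0.075,
              0.065, 0.055, 0.027, 0.011, 0.002),
    female_share = c(0.49, 0.49, 0.50, 0.50, 0.51, 0.52, 0.53, 0.55,
                     0.58, 0.62, 0.66, 0.70, 0.72))
}

## planted per-1,000 rates per class, shaped like the observed age gradients
.default_prevalence <- function()
  list(parkinsonism = c(0.8, 1.0, 2.0, 3.2, 5.9, 10.2, 16.3, 29.9, 43.8,
                        55.4, 54.2, 47.5, 35.0),
       dementia = c(1.5, 2.0, 3.0, 5.0, 9.0, 16.0, 30.0, 60.0, 100.0,
                    150.0, 190.0, 200.0, 200.0))

.default_incidence <- function()
  list(parkinsonism = c(0.3, 0.4, 0.7, 1.1, 1.8, 2.7, 3.8, 6.8, 8.6,
                        8.3, 8.4, 6.5, 3.7),
       dementia = c(0.6, 0.8, 1.2, 2.0, 3.5, 6.0, 10.0, 18.0, 28.0,
                    38.0, 45.0, 45.0, 40.0))

#' Configuration of the synthetic region
#'
#' Defaults state the world the generator emulates: an aging Italian region
#' observed 2016-2021 with age/sex-graded parkinsonism and dementia
#' prevalence and incidence (per-1,000, per 5-year class), a 29% dementia
#' comorbidity among parkinsonism cases, proxy-drug confounders among
#' non-cases (half of whom carry psychiatric labels), per-source detection
#' probabilities, repeated yearly tracer prescriptions, and per-class
#' mortality higher in cases.  See the methods vignette for the rationale
#' of each default.
#'
#' @param n_persons registry size (>= 1).
#' @param reference_year point-prevalence year (Dec 31), default 2021.
#' @param study_start first year of the observation window, default 2016.
#' @param seed integer seed; the whole fixture is a pure function of the
#'   config including this seed.
#' @param n_municipalities number of municipalities; populations are drawn
#'   log-uniform to create realistic small-area variance.
#' @param age_sex_structure data.frame `age_class`, `share` (sums to 1),
#'   `female_share`.
#' @param planted_prevalence,planted_annual_incidence lists with per-class
#'   per-1,000 vectors for `parkinsonism` and `dementia`.
#' @param comorbidity_fraction P(dementia | parkinsonism case).
#' @param confounder_fraction share of non-cases on repeated proxy drugs.
#' @param psychiatric_label_fraction share of confounders carrying a
#'   psychiatric exemption or discharge.
#' @param detection per-source detection probabilities
#'   `c(p_rx=, p_hdr=, p_exemption=)` (p_hdr applies to dementia
#'   case-years; p_exemption once at onset).
#' @param rx_repeat list `dist = "shifted_poisson"` with `min`, `mean`
#'   (yearly prescription count = min + Poisson(mean - min)) or
#'   `dist = "fixed"` with `count`.
#' @param mortality list `noncase` (per-class annual death probability) and
#'   `case_multiplier`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_persons = 20000L,
                       reference_year = 2021L,
                       study_start = 2016L,
                       seed = 1L,
                       n_municipalities = 30L,
                       age_sex_structure = .default_structure(),
                       planted_prevalence = .default_prevalence(),
                       planted_annual_incidence = .default_incidence(),
                       comorbidity_fraction = 0.29,
                       confounder_fraction = 0.04,
                       psychiatric_label_fraction = 0.5,
                       detection = c(p_rx = 0.9, p_hdr = 0.25,
                                     p_exemption = 0.2),
                       rx_repeat = list(dist = "shifted_poisson", min = 2L,
                                        mean = 6),
                       mortality = list(
                         noncase = c(0.001, 0.0015, 0.002, 0.003, 0.005,
                                     0.008, 0.012, 0.020, 0.040, 0.080,
                                     0.150, 0.250, 0.350),
                         case_multiplier = 1.5)) {
  cfg <- list(n_persons = as.integer(n_persons),
              reference_year = as.integer(reference_year),
              study_start = as.integer(study_start),
              seed = as.integer(seed),
              n_municipalities = as.integer(n_municipalities),
              age_sex_structure = as.data.table(age_sex_structure),
              planted_prevalence = planted_prevalence,
              planted_annual_incidence = planted_annual_incidence,
              comorbidity_fraction = comorbidity_fraction,
              confounder_fraction = confounder_fraction,
              psychiatric_label_fraction = psychiatric_label_fraction,
              detection = detection,
              rx_repeat = rx_repeat,
              mortality = mortality)
  if (cfg$n_persons <= 0L) stop("n_persons must be positive")
  if (cfg$study_start >= cfg$reference_year)
    stop("study_start must precede reference_year")
  if (abs(sum(cfg$age_sex_structure$share) - 1) > 1e-8)
    stop("age_sex_structure shares must sum to 1")
  probs <- c(cfg$detection, cfg$comorbidity_fraction,
             cfg$confounder_fraction, cfg$psychiatric_label_fraction,
             cfg$mortality$noncase)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (any(unlist(cfg$planted_prevalence) < 0) ||
      any(unlist(cfg$planted_annual_incidence) < 0))
    stop("planted rates must be >= 0")
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @param path YAML file.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$age_sex_structure))
    y$age_sex_structure <- data.table::rbindlist(
      lapply(y$age_sex_structure, as.data.table))
  if (!is.null(y$detection)) y$detection <- unlist(y$detection)
  do.call(sim_config, y)
}

#' @rdname sim_config
#' @param cfg a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  y <- unclass(cfg)
  y$age_sex_structure <- lapply(seq_len(nrow(cfg$age_sex_structure)),
                                function(i) as.list(cfg$age_sex_structure[i]))
  y$detection <- as.list(cfg$detection)
  yaml::write_yaml(y, path)
  invisible(path)
}

.draw_rx_count <- function(n, rx_repeat) {
  if (identical(rx_repeat$dist, "fixed")) rep(as.integer(rx_repeat$count), n)
  else rx_repeat$min + rpois(n, max(rx_repeat$mean - rx_repeat$min, 0))
}

#' Generate the population registry and the planted ground truth
#'
#' Draws `n_persons` residents aged >= 40 at the reference year end, with
#' class/sex shares from the configured structure, municipality assignment
#' with log-uniform municipality sizes, planted disease status (prevalent
#' onsets uniform over the 10 years before the reference year; incident
#' onsets in the reference year at the planted annual incidence), and
#' deaths applied year by year over the study window with case-elevated
#' hazards.  Persons dying before their onset never manifest and revert to
#' non-cases.
#'
#' @param cfg a [sim_config()].
#' @return list: `registry` (data.table in the registry schema) and `truth`
#'   (`person_id`, `true_status` in none/parkinsonism/dementia/both,
#'   `park_onset`, `dem_onset`, `onset_year`, `death_year`).
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_persons
  sc <- age_classes()
  st <- cfg$age_sex_structure
  ref_end <- as.Date(sprintf("%d-12-31", cfg$reference_year))

  ci <- sample.int(nrow(st), n, replace = TRUE, prob = st$share)
  sex <- ifelse(runif(n) < st$female_share[ci], "female", "male")
  lo <- sc$lower[ci]
  hi <- ifelse(is.finite(sc$upper[ci]), sc$upper[ci], 104)
  age_days <- runif(n, lo * 365.25, (hi + 1) * 365.25 - 1)
  birth_date <- ref_end - round(age_days)

  mun_w <- exp(runif(cfg$n_municipalities, log(1), log(100)))
  municipality_id <- sprintf("M%03d", sample.int(cfg$n_municipalities, n,
                                                 replace = TRUE,
                                                 prob = mun_w))
  person_id <- sprintf("P%07d", seq_len(n))

  ## planted disease status
  p_park <- cfg$planted_prevalence$parkinsonism[ci] / 1000
  p_dem <- cfg$planted_prevalence$dementia[ci] / 1000
  park <- runif(n) < p_park
  dem <- ifelse(park, runif(n) < cfg$comorbidity_fraction,
                runif(n) < p_dem)
  ## prevalent onsets: uniform over the 10 years preceding the reference
  ## year, so the look-back sees evidence on both sides of its window
  onset_prev <- function(is_case) {
    o <- rep(NA_integer_, n)
    k <- sum(is_case)
    o[is_case] <- cfg$reference_year - sample.int(10L, k, replace = TRUE)
    o
  }
  park_onset <- onset_prev(park)
  dem_onset <- onset_prev(dem)
  ## incident plants: disease-free persons whose first onset is the
  ## reference year itself
  i_park <- cfg$planted_annual_incidence$parkinsonism[ci] / 1000
  i_dem <- cfg$planted_annual_incidence$dementia[ci] / 1000
  new_park <- !park & !dem & runif(n) < i_park
  new_dem <- !park & !dem & !new_park & runif(n) < i_dem
  park <- park | new_park
  dem <- dem | new_dem
  park_onset[new_park] <- cfg$reference_year
  dem_onset[new_dem] <- cfg$reference_year

  ## deaths, year by year over the window
  qx <- cfg$mortality$noncase[ci]
  qx_case <- pmin(qx * cfg$mortality$case_multiplier, 0.9)
  death_year <- rep(NA_integer_, n)
  for (y in cfg$study_start:cfg$reference_year) {
    at_risk <- is.na(death_year)
    onset_by_y <- (park & !is.na(park_onset) & park_onset <= y) |
      (dem & !is.na(dem_onset) & dem_onset <= y)
    q <- ifelse(onset_by_y, qx_case, qx)
    dies <- at_risk & runif(n) < q
    death_year[dies] <- y
  }
  ## death before onset: the disease never manifests
  undo_park <- park & !is.na(death_year) & !is.na(park_onset) &
    death_year < park_onset
  undo_dem <- dem & !is.na(death_year) & !is.na(dem_onset) &
    death_year < dem_onset
  park[undo_park] <- FALSE; park_onset[undo_park] <- NA_integer_
  dem[undo_dem] <- FALSE; dem_onset[undo_dem] <- NA_integer_

  death_date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  has_d <- !is.na(death_year)
  death_date[has_d] <- as.Date(sprintf("%d-01-01", death_year[has_d])) +
    sample.int(365L, sum(has_d), replace = TRUE) - 1L

  registry <- data.table(
    person_id = person_id, sex = sex, birth_date = birth_date,
    death_date = death_date, municipality_id = municipality_id,
    residency_start = pmax(birth_date,
                           as.Date(sprintf("%d-01-01",
                                           cfg$study_start - 10L))),
    residency_end = as.Date(NA))

  status <- assign_group(park, dem)
  truth <- data.table(
    person_id = person_id, true_status = status,
    park_onset = park_onset, dem_onset = dem_onset,
    onset_year = pmin(park_onset, dem_onset, na.rm = TRUE),
    death_year = death_year)
  truth[true_status == "none", onset_year := NA_integer_]
  list(registry = registry, truth = truth)
}

## random dates within a calendar year, capped at a per-person last day
.dates_in_year <- function(year, last_day) {
  start <- as.Date(sprintf("%d-01-01", year))
  span <- pmin(as.numeric(last_day - start) + 1, 365)
  start + floor(runif(length(year)) * pmax(span, 1))
}

#' Emit prescription, discharge and exemption events
#'
#' For every case and calendar year from onset to death/window end, emits
#' tracer prescriptions with probability `p_rx` (yearly counts from
#' `rx_repeat`, so treated case-years meet the repeated-prescription rule),
#' dementia discharges with `p_hdr`, and a one-off exemption at onset with
#' `p_exemption`.  Tracer ATC codes are drawn per case from subgroup mixes
#' dominated, for dementia, by the proxy drugs (antipsychotics, trazodone,
#' mirtazapine).  Confounders — non-cases on repeated proxy drugs — emit
#' proxy prescriptions from a start year to the window end; the configured
#' fraction of them carries a psychiatric exemption or discharge.  All
#' events fall within residency and before death.
#'
#' @param registry,truth outputs of [generate_population()].
#' @param cfg the same [sim_config()].
#' @return list of `prescriptions`, `discharges`, `exemptions` data.tables
#'   in the source schemas.
#' @export
emit_events <- function(registry, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  reg <- as.data.table(registry)
  tr <- as.data.table(truth)
  stopifnot(identical(reg$person_id, tr$person_id))
  win_end <- cfg$reference_year
  last_day <- data.table::fifelse(is.na(reg$death_date),
                                  as.Date(sprintf("%d-12-31", win_end)),
                                  reg$death_date)

  park_mix <- c(N04BA02 = 0.62, N04BC05 = 0.38)
  dem_mix <- c(N06DA02 = 0.049, N06DX01 = 0.047, N05AH04 = 0.535,
               N06AX05 = 0.264, N06AX11 = 0.107)
  dem_mix <- dem_mix / sum(dem_mix)
  proxy_mix <- c(N05AH04 = 0.55, N06AX05 = 0.30, N06AX11 = 0.15)

  rx_out <- list(); hdr_out <- list(); ex_out <- list()
  case_years <- function(onset) {
    idx <- which(!is.na(onset))
    if (!length(idx)) return(NULL)
    dy <- tr$death_year[idx]
    to <- data.table::fifelse(is.na(dy), win_end, pmin(dy, win_end))
    cy <- data.table(i = rep(idx, to - onset[idx] + 1L))
    cy[, year := {
      o <- onset[i[1]]; o:(o + .N - 1L)
    }, by = i]
    cy
  }
  emit_disease <- function(onset, mix, disease) {
    cy <- case_years(onset)
    if (is.null(cy) || nrow(cy) == 0L) return(invisible())
    ## per-case primary drug, constant across years
    idx <- unique(cy$i)
    drug <- setNames(sample(names(mix), length(idx), replace = TRUE,
                            prob = mix), as.character(idx))
    ## prescriptions
    det <- cy[runif(.N) < cfg$detection[["p_rx"]]]
    if (nrow(det)) {
      k <- .draw_rx_count(nrow(det), cfg$rx_repeat)
      long <- det[rep(seq_len(.N), k)]
      rx_out[[length(rx_out) + 1L]] <<- data.table(
        person_id = reg$person_id[long$i],
        dispense_date = .dates_in_year(long$year, last_day[long$i]),
        atc_code = unname(drug[as.character(long$i)]))
    }
    ## discharges (dementia only)
    if (disease == "dementia" && cfg$detection[["p_hdr"]] > 0) {
      h <- cy[runif(.N) < cfg$detection[["p_hdr"]]]
      if (nrow(h)) {
        adm <- .dates_in_year(h$year, last_day[h$i] - 3L)
        hdr_out[[length(hdr_out) + 1L]] <<- data.table(
          person_id = reg$person_id[h$i],
          admission_date = adm,
          discharge_date = adm + sample.int(12L, nrow(h), replace = TRUE),
          dx1 = sample(c("3310", "290", "2941", "29011"), nrow(h),
                       replace = TRUE),
          dx2 = data.table::fifelse(runif(nrow(h)) < 0.4, "4019", NA_character_),
          dx3 = NA_character_, dx4 = NA_character_, dx5 = NA_character_,
          dx6 = NA_character_)
      }
    }
    ## exemption at onset
    e <- which(!is.na(onset) & runif(length(onset)) <
                 cfg$detection[["p_exemption"]])
    if (length(e)) {
      code <- if (disease == "parkinsonism") "038" else "011"
      ex_out[[length(ex_out) + 1L]] <<- data.table(
        person_id = reg$person_id[e],
        exemption_code = code,
        start_date = .dates_in_year(onset[e], last_day[e]))
    }
    invisible()
  }
  park_onset <- data.table::fifelse(
    tr$true_status %in% c("parkinsonism", "both"), tr$park_onset,
    NA_integer_)
  dem_onset <- data.table::fifelse(
    tr$true_status %in% c("dementia", "both"), tr$dem_onset, NA_integer_)
  emit_disease(park_onset, park_mix, "parkinsonism")
  emit_disease(dem_onset, dem_mix, "dementia")

  ## confounders: non-cases on repeated proxy drugs
  nc <- which(tr$true_status == "none")
  conf <- nc[runif(length(nc)) < cfg$confounder_fraction]
  if (length(conf)) {
    start_y <- cfg$study_start +
      floor(runif(length(conf)) * (win_end - cfg$study_start + 1L))
    ## only emit while alive
    dy <- tr$death_year[conf]
    ok <- is.na(dy) | dy >= start_y
    conf <- conf[ok]; start_y <- start_y[ok]
    if (length(conf)) {
      onset_c <- rep(NA_integer_, nrow(tr))
      onset_c[conf] <- start_y
      cy <- case_years(onset_c)
      drug <- setNames(sample(names(proxy_mix), length(conf), replace = TRUE,
                              prob = proxy_mix), as.character(conf))
      k <- .draw_rx_count(nrow(cy), cfg$rx_repeat)
      long <- cy[rep(seq_len(.N), k)]
      rx_out[[length(rx_out) + 1L]] <- data.table(
        person_id = reg$person_id[long$i],
        dispense_date = .dates_in_year(long$year, last_day[long$i]),
        atc_code = unname(drug[as.character(long$i)]))
      ## psychiatric labels on a fraction of confounders
      lab <- conf[runif(length(conf)) < cfg$psychiatric_label_fraction]
      if (length(lab)) {
        as_ex <- runif(length(lab)) < 0.5
        if (any(as_ex))
          ex_out[[length(ex_out) + 1L]] <- data.table(
            person_id = reg$person_id[lab[as_ex]],
            exemption_code = "044",
            start_date = .dates_in_year(
              pmax(cfg$study_start, onset_c[lab[as_ex]] - 1L),
              last_day[lab[as_ex]]))
        if (any(!as_ex)) {
          li <- lab[!as_ex]
          adm <- .dates_in_year(pmax(cfg$study_start, onset_c[li] - 1L),
                                last_day[li] - 3L)
          hdr_out[[length(hdr_out) + 1L]] <- data.table(
            person_id = reg$person_id[li],
            admission_date = adm,
            discharge_date = adm + sample.int(12L, length(li),
                                              replace = TRUE),
            dx1 = sample(c("2950", "2962"), length(li), replace = TRUE),
            dx2 = NA_character_, dx3 = NA_character_, dx4 = NA_character_,
            dx5 = NA_character_, dx6 = NA_character_)
        }
      }
    }
  }

  empty_rx <- data.table(person_id = character(0),
                         dispense_date = as.Date(character(0)),
                         atc_code = character(0))
  empty_hdr <- data.table(person_id = character(0),
                          admission_date = as.Date(character(0)),
                          discharge_date = as.Date(character(0)),
                          dx1 = character(0), dx2 = character(0),
                          dx3 = character(0), dx4 = character(0),
                          dx5 = character(0), dx6 = character(0))
  empty_ex <- data.table(person_id = character(0),
                         exemption_code = character(0),
                         start_date = as.Date(character(0)))
  cat_or <- function(lst, empty) {
    if (length(lst)) {
      out <- data.table::rbindlist(lst)
      data.table::setorder(out, person_id)
      out
    } else empty
  }
  list(prescriptions = cat_or(rx_out, empty_rx),
       discharges = cat_or(hdr_out, empty_hdr),
       exemptions = cat_or(ex_out, empty_ex))
}

#' Simulate a complete region
#'
#' Convenience wrapper: population + ground truth + events + linked
#' database.
#'
#' @param cfg a [sim_config()].
#' @return list: `registry`, `truth`, `events` (list of three tables) and
#'   `db` (an `event_db`).
#' @export
simulate_region <- function(cfg) {
  pop <- generate_population(cfg)
  ev <- emit_events(pop$registry, pop$truth, cfg)
  db <- build_histories(pop$registry, ev$prescriptions, ev$discharges,
                        ev$exemptions)
  list(registry = pop$registry, truth = pop$truth, events = ev, db = db)
}

#' Write a synthetic fixture to disk
#'
#' Writes the four source CSVs plus `truth.csv`
#' (`person_id,true_status,onset_year,death_year`); file contents are a
#' pure function of the config (fixed seed).
#'
#' @param out_dir output directory (created if needed).
#' @param registry,events,truth outputs of the generators.
#' @return character vector of the five file paths, invisibly.
#' @export
write_fixture <- function(out_dir, registry, events, truth) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("registry.csv", "prescriptions.csv",
                                "discharges.csv", "exemptions.csv",
                                "truth.csv"))
  write_source(registry, paths[1], "registry")
  write_source(events$prescriptions, paths[2], "prescriptions")
  write_source(events$discharges, paths[3], "discharges")
  write_source(events$exemptions, paths[4], "exemptions")
  data.table::fwrite(
    as.data.table(truth)[, .(person_id, true_status, onset_year,
                             death_year)],
    paths[5], na = "", quote = FALSE)
  invisible(paths)
}
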