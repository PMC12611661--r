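## Tracer-based case adjudication: parkinsonism via antiparkinsonian
## prescriptions or the Parkinson exemption; dementia via anti-dementia
## drugs, dementia ICD-9 discharges, dementia exemptions, or the
## antipsychotic/trazodone/mirtazapine proxy criterion with its psychiatric
## exclusion.  Incident cases require a disease-free look-back.

#' Code sets and repeat-prescription parameters for case adjudication
#'
#' The adjudication rules are driven entirely by configurable code sets
#' (exact regional lists vary and are reviewed by neurologists; the defaults
#' here are clearly-editable, documented stand-ins).  ATC and ICD-9 sets are
#' matched by prefix; ICD-9 codes are compared with dots stripped, so
#' `"294.1"` and `"2941"` are equivalent.
#'
#' @param park_atc ATC prefixes of antiparkinsonian tracer drugs (levodopa
#'   combinations N04BA, dopamine agonists N04BC, plus the other N04
#'   subgroups in clinical use).
#' @param park_exemption exemption code(s) specific for Parkinson's disease
#'   (Italian NHS code 038).
#' @param dementia_atc ATC prefixes of symptomatic anti-dementia drugs
#'   (anticholinesterases N06DA, memantine N06DX01).
#' @param proxy_atc ATC prefixes of the proxy tracers: antipsychotics (N05A)
#'   and the antidepressants trazodone (N06AX05) and mirtazapine (N06AX11).
#' @param dementia_icd9 ICD-9-CM prefixes for dementia discharge diagnoses.
#' @param dementia_exemption dementia-related exemption code(s).
#' @param psych_icd9 ICD-9-CM prefixes for the psychiatric disorders that
#'   veto the proxy criterion (schizophrenia 295, affective psychoses 296).
#' @param psych_exemption psychiatric exemption code(s).
#' @param repeat_min_count minimum number of matching prescriptions for
#'   "repeated"/"non-occasional" use; must be >= 2.
#' @param repeat_window_days span (days, closed interval) within which the
#'   `repeat_min_count` prescriptions must fall.
#' @return object of class `codebook`.
#' @export
codebook <- function(park_atc = c("N04BA", "N04BC", "N04BB", "N04BD",
                                  "N04BX", "N04AA"),
                     park_exemption = "038",
                     dementia_atc = c("N06DA", "N06DX01"),
                     proxy_atc = c("N05A", "N06AX05", "N06AX11"),
                     dementia_icd9 = c("290", "294.1", "294.2", "331.0",
                                       "331.1", "331.82"),
                     dementia_exemption = "011",
                     psych_icd9 = c("295", "296"),
                     psych_exemption = c("044", "046"),
                     repeat_min_count = 2L,
                     repeat_window_days = 365L) {
  cb <- list(park_atc = toupper(park_atc),
             park_exemption = as.character(park_exemption),
             dementia_atc = toupper(dementia_atc),
             proxy_atc = toupper(proxy_atc),
             dementia_icd9 = as.character(dementia_icd9),
             dementia_exemption = as.character(dementia_exemption),
             psych_icd9 = as.character(psych_icd9),
             psych_exemption = as.character(psych_exemption),
             repeat_min_count = as.integer(repeat_min_count),
             repeat_window_days = as.integer(repeat_window_days))
  if (cb$repeat_min_count < 2L)
    stop("repeat_min_count must be >= 2 ('repeated' excludes single use)")
  for (s in c("park_atc", "park_exemption", "dementia_atc", "proxy_atc",
              "dementia_icd9", "dementia_exemption"))
    if (length(cb[[s]]) == 0L) stop("code set must be non-empty: ", s)
  structure(cb, class = "codebook")
}

#' @rdname codebook
#' @param path YAML file with the codebook fields.
#' @export
read_codebook <- function(path) {
  do.call(codebook, yaml::read_yaml(path))
}

#' @rdname codebook
#' @param cb a `codebook`.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  yaml::write_yaml(unclass(cb), path)
  invisible(path)
}

## prefix matching helpers
.match_prefix <- function(codes, prefixes) {
  m <- rep(FALSE, length(codes))
  for (p in prefixes) m <- m | startsWith(codes, p)
  m & !is.na(codes)
}
.match_atc <- function(codes, prefixes)
  .match_prefix(toupper(codes), toupper(prefixes))
.match_icd9 <- function(codes, prefixes)
  .match_prefix(gsub(".", "", codes, fixed = TRUE),
                gsub(".", "", prefixes, fixed = TRUE))

## Earliest date of the first qualifying span of >= k matching prescriptions
## within w days, per person.  Returns data.table(person_id, first_date) for
## qualifying persons only.
.repeat_first_date <- function(dt, atc_set, k, w) {
  empty <- data.table(person_id = character(0),
                      first_date = as.Date(character(0)))
  if (nrow(dt) == 0L) return(empty)
  m <- dt[.match_atc(atc_code, atc_set)]
  if (nrow(m) == 0L) return(empty)
  data.table::setorder(m, person_id, dispense_date)
  m[, {
    d <- dispense_date
    if (length(d) < k) list(first_date = as.Date(NA)) else {
      span <- as.numeric(d[seq.int(k, length(d))] -
                           d[seq.int(1L, length(d) - k + 1L)])
      i <- which(span <= w)
      list(first_date = if (length(i)) d[i[1L]] else as.Date(NA))
    }
  }, by = person_id][!is.na(first_date)]
}

#' Repeated ("non-occasional") prescription rule
#'
#' TRUE iff at least `repeat_min_count` prescriptions matching any ATC
#' prefix in `atc_set` fall within some `repeat_window_days`-day span; the
#' qualifying date is the first prescription of the earliest such span.
#' This is the weakest reading of "repeated" that still excludes single,
#' occasional use.
#'
#' @param prescriptions data.frame/data.table with `dispense_date` and
#'   `atc_code` (one person), date-sorted.
#' @param atc_set ATC prefixes.
#' @param cb a [codebook()] supplying the repeat parameters.
#' @return list with `qualifies` (logical) and `first_date` (Date or NA).
#' @export
qualifies_repeated <- function(prescriptions, atc_set, cb) {
  dt <- as.data.table(prescriptions)
  if (!("person_id" %in% names(dt))) dt[, person_id := "x"]
  res <- .repeat_first_date(dt, atc_set, cb$repeat_min_count,
                            cb$repeat_window_days)
  list(qualifies = nrow(res) > 0L,
       first_date = if (nrow(res)) res$first_date[1L] else as.Date(NA))
}

## ---- vectorized criterion engine ------------------------------------------

## Long table of ALL disqualifying/qualifying evidence dates <= as_of:
## any single matching tracer or proxy prescription, dementia discharge, or
## parkinsonism/dementia exemption.  One row per matching record.
.evidence_dates <- function(db, cb, as_of) {
  rx <- db$prescriptions[dispense_date <= as_of]
  hdr <- db$discharges[admission_date <= as_of]
  ex <- db$exemptions[start_date <= as_of]
  ev <- list(
    if (nrow(rx)) rx[.match_atc(atc_code, c(cb$park_atc, cb$dementia_atc,
                                            cb$proxy_atc)),
                     .(person_id, evid_date = dispense_date)],
    if (nrow(hdr)) {
      dxm <- Reduce(`|`, lapply(paste0("dx", 1:6), function(cn)
        .match_icd9(hdr[[cn]], cb$dementia_icd9)))
      hdr[dxm, .(person_id, evid_date = admission_date)]
    },
    if (nrow(ex)) ex[exemption_code %in% c(cb$park_exemption,
                                           cb$dementia_exemption),
                     .(person_id, evid_date = start_date)]
  )
  ev <- data.table::rbindlist(ev[!vapply(ev, is.null, TRUE)])
  if (nrow(ev) == 0L)
    ev <- data.table(person_id = character(0),
                     evid_date = as.Date(character(0)))
  ev
}

## One row per registry person with, per criterion, the earliest qualifying
## date (NA if not met by as_of), the psychiatric flag (entire history, no
## time bound), and first_any = earliest single-record evidence date.
.criteria_table <- function(db, cb, as_of) {
  reg <- db$registry
  rx <- db$prescriptions[dispense_date <= as_of]
  hdr <- db$discharges[admission_date <= as_of]
  ex <- db$exemptions[start_date <= as_of]

  first_of <- function(x, col) {
    if (nrow(x) == 0L)
      return(data.table(person_id = character(0),
                        first_date = as.Date(character(0))))
    x[, .(first_date = min(get(col))), by = person_id]
  }
  k <- cb$repeat_min_count; w <- cb$repeat_window_days

  crit <- list(
    park_rx = .repeat_first_date(rx, cb$park_atc, k, w),
    park_exemption = first_of(ex[exemption_code %in% cb$park_exemption],
                              "start_date"),
    dem_rx = .repeat_first_date(rx, cb$dementia_atc, k, w),
    dem_hdr = {
      if (nrow(hdr) == 0L) {
        data.table(person_id = character(0),
                   first_date = as.Date(character(0)))
      } else {
        dxm <- Reduce(`|`, lapply(paste0("dx", 1:6), function(cn)
          .match_icd9(hdr[[cn]], cb$dementia_icd9)))
        first_of(hdr[dxm], "admission_date")
      }
    },
    dem_exemption = first_of(ex[exemption_code %in% cb$dementia_exemption],
                             "start_date"),
    dem_proxy = .repeat_first_date(rx, cb$proxy_atc, k, w)
  )

  out <- data.table(person_id = reg$person_id)
  for (nm in names(crit)) {
    dt <- crit[[nm]]
    data.table::setnames(dt, "first_date", nm)
    out <- dt[out, on = "person_id"]
  }

  ## psychiatric labels scan the entire available history
  psych_ids <- character(0)
  if (nrow(db$exemptions))
    psych_ids <- db$exemptions[exemption_code %in% cb$psych_exemption,
                               unique(person_id)]
  if (nrow(db$discharges)) {
    pm <- Reduce(`|`, lapply(paste0("dx", 1:6), function(cn)
      .match_icd9(db$discharges[[cn]], cb$psych_icd9)))
    psych_ids <- union(psych_ids, db$discharges[pm, unique(person_id)])
  }
  out[, psych := person_id %in% psych_ids]

  ev <- .evidence_dates(db, cb, as_of)
  if (nrow(ev)) {
    fa <- ev[, .(first_any = min(evid_date)), by = person_id]
    out <- fa[out, on = "person_id"]
  } else out[, first_any := as.Date(NA)]
  data.table::setcolorder(out, "person_id")
  out[]
}

## classification from a criteria table: park/dem flags, group, first dates,
## psychiatric-exclusion flag.  Dementia: any core criterion, or proxy
## without psychiatric labels; proxy-only candidates with psychiatric labels
## are excluded.
.classify <- function(ct) {
  ct <- data.table::copy(ct)
  pmin_date <- function(...) {
    m <- do.call(pmin, c(list(...), na.rm = TRUE))
    as.Date(m, origin = "1970-01-01")
  }
  ct[, park := !is.na(park_rx) | !is.na(park_exemption)]
  ct[, dem_core := !is.na(dem_rx) | !is.na(dem_hdr) | !is.na(dem_exemption)]
  ct[, dem := dem_core | (!is.na(dem_proxy) & !psych)]
  ct[, excluded_psychiatric := !dem_core & !is.na(dem_proxy) & psych]
  ct[, park_first := pmin_date(park_rx, park_exemption)]
  ct[, dem_first := data.table::fifelse(
    dem, pmin_date(dem_rx, dem_hdr, dem_exemption, dem_proxy), as.Date(NA))]
  ct[, group := assign_group(park, dem)]
  ct[]
}

#' Classify one person's parkinsonism status
#'
#' Parkinsonism holds iff (i) repeated antiparkinsonian prescriptions or
#' (ii) a Parkinson-specific exemption is present by `as_of`.
#'
#' @param history an `event_history` from [person_history()].
#' @param cb a [codebook()].
#' @param as_of censoring date; events after it are ignored.
#' @return list: `case` (logical), `criteria` met, `sources` contributing,
#'   `first_date` earliest evidence across met criteria.
#' @export
classify_parkinsonism <- function(history, cb, as_of) {
  ct <- .classify(.criteria_table(.history_as_db(history), cb,
                                  as.Date(as_of)))
  met <- c("park_rx", "park_exemption")[
    c(!is.na(ct$park_rx), !is.na(ct$park_exemption))]
  src <- c(park_rx = "prescription", park_exemption = "exemption")
  list(case = ct$park, criteria = met,
       sources = unique(unname(src[met])), first_date = ct$park_first)
}

#' Classify one person's dementia status
#'
#' Dementia holds iff any of: (i) repeated anti-dementia prescriptions,
#' (ii) a discharge with a dementia ICD-9 code in any of the six diagnosis
#' positions, (iii) a dementia exemption, (iv) repeated proxy-drug use
#' (antipsychotics, trazodone, mirtazapine).  When ONLY (iv) applies, any
#' psychiatric discharge or exemption anywhere in the history vetoes the
#' case (`excluded_psychiatric`); criteria (i)-(iii) are never vetoed.
#'
#' @inheritParams classify_parkinsonism
#' @return list: `case`, `criteria`, `sources`, `first_date`,
#'   `excluded_psychiatric`.
#' @export
classify_dementia <- function(history, cb, as_of) {
  ct <- .classify(.criteria_table(.history_as_db(history), cb,
                                  as.Date(as_of)))
  all_crit <- c("dem_rx", "dem_hdr", "dem_exemption", "dem_proxy")
  met <- all_crit[!vapply(all_crit, function(cn) is.na(ct[[cn]]), TRUE)]
  if (!ct$dem) met <- character(0)
  src_map <- c(dem_rx = "prescription", dem_hdr = "discharge",
               dem_exemption = "exemption", dem_proxy = "prescription")
  list(case = ct$dem, criteria = met,
       sources = unique(unname(src_map[met])),
       first_date = ct$dem_first,
       excluded_psychiatric = ct$excluded_psychiatric)
}

#' Combine disease flags into the three analysis groups
#'
#' @param park,dem logical vectors.
#' @return character vector: `"parkinsonism"`, `"dementia"`, `"both"`
#'   (the intersection group) or `"none"`.
#' @export
assign_group <- function(park, dem) {
  data.table::fcase(park & dem, "both",
                    park & !dem, "parkinsonism",
                    !park & dem, "dementia",
                    default = "none")
}

#' Disease-free look-back (washout) for incident status
#'
#' A case with evidence in `year` is incident iff no qualifying evidence of
#' neurodegenerative disease — any matching prescription (including a
#' single one and including proxy drugs), dementia discharge, or
#' parkinsonism/dementia exemption — exists in calendar years
#' `[year - lookback_years, year - 1]`.  With a study window starting after
#' `year - lookback_years` the look-back is effectively truncated at the
#' study start (early reference years get a correspondingly shorter
#' washout).
#'
#' @param history an `event_history`; must have evidence dated in `year`.
#' @param cb a [codebook()].
#' @param year calendar year of the (first) new evidence.
#' @param lookback_years washout length, default 5.
#' @return logical.
#' @export
is_incident <- function(history, cb, year, lookback_years = 5L) {
  as_of <- as.Date(sprintf("%d-12-31", year))
  ev <- .evidence_dates(.history_as_db(history), cb, as_of)$evid_date
  if (!any(format(ev, "%Y") == as.character(year)))
    stop("contract violation: no qualifying evidence in ", year)
  lo <- as.Date(sprintf("%d-01-01", year - lookback_years))
  hi <- as.Date(sprintf("%d-12-31", year - 1L))
  !any(ev >= lo & ev <= hi)
}

#' Identify the case cohort at a reference year
#'
#' Runs the full adjudication over a linked database: classifies every
#' person as of Dec 31 of `reference_year`, keeps those alive and resident
#' on that date as the prevalent cohort, flags incident cases via the
#' disease-free look-back, and tabulates the contribution of the three
#' sources and of the tracer-drug ATC subgroups (the inputs of the usual
#' source-overlap and drug-share figures).  Cases that died during the
#' reference year are returned separately for mortality estimation.
#'
#' @param db an `event_db`.
#' @param cb a [codebook()].
#' @param reference_year calendar year; adjudication is censored at Dec 31.
#' @param lookback_years washout length for the incident flag (default 5;
#'   effectively truncated by the available history for early years).
#' @return object of class `case_cohort`: list with
#'   \describe{
#'     \item{cases}{data.table, one row per prevalent case: `person_id`,
#'       `group`, `sources`, `criteria_met` (both `;`-separated),
#'       `first_evidence_date`, `incident`, `excluded_psychiatric`
#'       (always FALSE for included cases).}
#'     \item{deaths}{cases (same columns) whose death fell in the reference
#'       year; disjoint from `cases`.}
#'     \item{excluded}{proxy-only candidates vetoed by psychiatric labels.}
#'     \item{source_breakdown}{prevalent cases per group and contributing
#'       source.}
#'     \item{drug_breakdown}{per-ATC-subgroup shares among drug-identified
#'       cases, per disease.}
#'     \item{counts}{stage ledger: linked, classified, excluded_psychiatric,
#'       prevalent, incident.}
#'   }
#' @export
identify_cohort <- function(db, cb, reference_year, lookback_years = 5L) {
  stopifnot(inherits(db, "event_db"), inherits(cb, "codebook"))
  as_of <- as.Date(sprintf("%d-12-31", reference_year))
  ct <- .classify(.criteria_table(db, cb, as_of))

  reg <- db$registry
  ct <- reg[, .(person_id, birth_date, death_date, municipality_id,
                residency_start, residency_end, sex)][ct, on = "person_id"]
  ct[, alive := is.na(death_date) | death_date >= as_of]
  ct[, resident := (is.na(residency_start) | residency_start <= as_of) &
       (is.na(residency_end) | residency_end >= as_of)]
  ct[, died_in_year := !is.na(death_date) &
       death_date >= as.Date(sprintf("%d-01-01", reference_year)) &
       death_date <= as_of]
  ct[, is_case := group != "none"]

  ## incident: evidence in the reference year, none in the look-back window
  ev <- .evidence_dates(db, cb, as_of)
  lo <- as.Date(sprintf("%d-01-01", reference_year - lookback_years))
  hi <- as.Date(sprintf("%d-12-31", reference_year - 1L))
  y0 <- as.Date(sprintf("%d-01-01", reference_year))
  flags <- if (nrow(ev)) {
    ev[, .(in_ref = any(evid_date >= y0),
           in_lb = any(evid_date >= lo & evid_date <= hi)),
       by = person_id]
  } else data.table(person_id = character(0), in_ref = logical(0),
                    in_lb = logical(0))
  ct <- flags[ct, on = "person_id"]
  ct[, incident := is_case & !is.na(in_ref) & in_ref & !in_lb]

  crit_cols <- c("park_rx", "park_exemption", "dem_rx", "dem_hdr",
                 "dem_exemption", "dem_proxy")
  src_map <- c(park_rx = "prescription", park_exemption = "exemption",
               dem_rx = "prescription", dem_hdr = "discharge",
               dem_exemption = "exemption", dem_proxy = "prescription")
  empty_rec <- data.table(person_id = character(0), group = character(0),
                          sources = character(0),
                          criteria_met = character(0),
                          first_evidence_date = as.Date(character(0)),
                          incident = logical(0),
                          excluded_psychiatric = logical(0))
  mk_records <- function(idx) {
    if (!length(idx)) return(data.table::copy(empty_rec))
    sub <- ct[idx]
    ## criteria contribute only to the disease(s) the person actually has
    longs <- lapply(crit_cols, function(cn) {
      act <- !is.na(sub[[cn]])
      act <- act & if (cn %in% c("park_rx", "park_exemption")) sub$park
                   else sub$dem
      data.table(person_id = sub$person_id[act], criterion = cn)
    })
    long <- data.table::rbindlist(longs)
    long[, criterion := factor(criterion, levels = crit_cols)]
    agg <- long[order(person_id, criterion),
                .(criteria_met = paste(criterion, collapse = ";"),
                  sources = paste(sort(unique(unname(
                    src_map[as.character(criterion)]))), collapse = ";")),
                by = person_id]
    rec <- data.table(
      person_id = sub$person_id,
      group = sub$group,
      first_evidence_date = as.Date(
        pmin(as.numeric(sub$park_first), as.numeric(sub$dem_first),
             na.rm = TRUE), origin = "1970-01-01"),
      incident = sub$incident,
      excluded_psychiatric = FALSE)
    rec <- agg[rec, on = "person_id"]
    data.table::setcolorder(rec, names(empty_rec))
    rec[]
  }
  prev_idx <- which(ct$is_case & ct$alive & ct$resident)
  death_idx <- which(ct$is_case & ct$died_in_year & !(ct$alive & ct$resident))
  cases <- mk_records(prev_idx)
  deaths <- mk_records(death_idx)
  excluded <- ct[excluded_psychiatric & group == "none",
                 .(person_id, excluded_psychiatric)]

  sb <- if (nrow(cases)) {
    long <- cases[, .(source = unlist(strsplit(sources, ";", fixed = TRUE))),
                  by = .(person_id, group)]
    long[, .(cases = .N), by = .(group, source)][order(group, source)]
  } else data.table(group = character(0), source = character(0),
                    cases = integer(0))

  structure(list(
    cases = cases, deaths = deaths, excluded = excluded,
    source_breakdown = sb,
    drug_breakdown = .drug_breakdown(db, cb, cases, as_of),
    reference_year = reference_year, lookback_years = lookback_years,
    counts = c(linked = nrow(reg),
               classified = sum(ct$is_case),
               excluded_psychiatric = nrow(excluded),
               prevalent = nrow(cases),
               incident = sum(cases$incident))),
    class = "case_cohort")
}

## Per-disease ATC-subgroup shares among drug-identified prevalent cases:
## each case contributes the subgroup of its earliest matching prescription.
.drug_breakdown <- function(db, cb, cases, as_of) {
  empty <- data.table(disease = character(0), subgroup = character(0),
                      n = integer(0), share = numeric(0))
  if (nrow(cases) == 0L || nrow(db$prescriptions) == 0L) return(empty)
  rx <- db$prescriptions[dispense_date <= as_of]
  one <- function(ids, atc_set, labeller) {
    m <- rx[person_id %in% ids & .match_atc(atc_code, atc_set)]
    if (nrow(m) == 0L) return(NULL)
    first <- m[order(person_id, dispense_date), .SD[1L], by = person_id]
    first[, subgroup := labeller(toupper(atc_code))]
    agg <- first[, .(n = .N), by = subgroup]
    agg[, share := n / sum(n)]
    agg[order(-n)]
  }
  pk <- one(cases[group %in% c("parkinsonism", "both"), person_id],
            cb$park_atc,
            function(a) data.table::fcase(
              startsWith(a, "N04BA"), "dopa and derivatives (N04BA)",
              startsWith(a, "N04BC"), "dopamine agonists (N04BC)",
              default = "other antiparkinsonian"))
  dm <- one(cases[group %in% c("dementia", "both"), person_id],
            c(cb$dementia_atc, cb$proxy_atc),
            function(a) data.table::fcase(
              startsWith(a, "N06DA"), "anticholinesterase (N06DA)",
              startsWith(a, "N06DX01"), "memantine (N06DX01)",
              startsWith(a, "N05A"), "antipsychotic (N05A)",
              startsWith(a, "N06AX05"), "trazodone (N06AX05)",
              startsWith(a, "N06AX11"), "mirtazapine (N06AX11)",
              default = "other"))
  rbind(if (!is.null(pk)) cbind(disease = "parkinsonism", pk),
        if (!is.null(dm)) cbind(disease = "dementia", dm))
}

#' @export
print.case_cohort <- function(x, ...) {
  cat(sprintf("Case cohort, reference year %d (look-back %d y)\n",
              x$reference_year, x$lookback_years))
  print(x$counts)
  if (nrow(x$cases))
    print(x$cases[, .N, by = group][order(group)])
  invisible(x)
}

#' Write adjudicated cases to CSV
#'
#' @param cohort a `case_cohort`.
#' @param path output path (`cases.csv`).
#' @export
write_cases <- function(cohort, path) {
  stopifnot(inherits(cohort, "case_cohort"))
  data.table::fwrite(cohort$cases, path, dateTimeAs = "ISO", na = "",
                     quote = FALSE)
  invisible(path)
}
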