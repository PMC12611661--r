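## Small in-code fixture builders shared across tests.

library(data.table)

d <- function(x) as.Date(x)

mk_registry <- function(ids, sex = "female", birth = "1950-06-15",
                        death = NA, mun = "M001",
                        res_start = "1990-01-01", res_end = NA) {
  data.table(person_id = ids,
             sex = rep_len(sex, length(ids)),
             birth_date = d(rep_len(birth, length(ids))),
             death_date = d(rep_len(death, length(ids))),
             municipality_id = rep_len(mun, length(ids)),
             residency_start = d(rep_len(res_start, length(ids))),
             residency_end = d(rep_len(res_end, length(ids))))
}

mk_rx <- function(id, dates, atc = "N04BA02") {
  data.table(person_id = rep_len(id, length(dates)),
             dispense_date = d(dates),
             atc_code = rep_len(atc, length(dates)))
}

mk_hdr <- function(id, adm, dx1 = "3310", dx = NULL) {
  out <- data.table(person_id = rep_len(id, length(adm)),
                    admission_date = d(adm),
                    discharge_date = d(adm) + 5L,
                    dx1 = rep_len(dx1, length(adm)),
                    dx2 = NA_character_, dx3 = NA_character_,
                    dx4 = NA_character_, dx5 = NA_character_,
                    dx6 = NA_character_)
  if (!is.null(dx)) for (j in seq_along(dx)) out[[paste0("dx", j)]] <- dx[j]
  out
}

mk_ex <- function(id, dates, code = "038") {
  data.table(person_id = rep_len(id, length(dates)),
             exemption_code = rep_len(code, length(dates)),
             start_date = d(dates))
}

empty_rx <- function() mk_rx(character(0), character(0))[0]
empty_hdr <- function() mk_hdr(character(0), character(0))[0]
empty_ex <- function() mk_ex(character(0), character(0))[0]

## a db from pieces, defaulting to empty event tables
mk_db <- function(registry, rx = empty_rx(), hdr = empty_hdr(),
                  ex = empty_ex()) {
  suppressWarnings(build_histories(registry, rx, hdr, ex))
}

## brute-force oracle for the repeated-prescription rule: enumerate all
## k-subsets ordered by date and test the span directly
oracle_repeated <- function(dates, k, w) {
  dates <- sort(dates)
  if (length(dates) < k) return(list(qualifies = FALSE,
                                     first_date = as.Date(NA)))
  combs <- utils::combn(seq_along(dates), k)
  ok <- apply(combs, 2, function(ix)
    as.numeric(dates[max(ix)] - dates[min(ix)]) <= w)
  if (!any(ok)) return(list(qualifies = FALSE, first_date = as.Date(NA)))
  starts <- dates[apply(combs[, ok, drop = FALSE], 2, min)]
  list(qualifies = TRUE, first_date = min(starts))
}

## quick simulated region used by several files
small_sim <- function(n = 4000, seed = 7, ...) {
  simulate_region(sim_config(n_persons = n, seed = seed, ...))
}
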