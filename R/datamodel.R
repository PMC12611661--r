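## Record schemas, CSV readers/writers, pseudonymization, event-history
## assembly.  All tabular data are data.tables with Date columns; dates are
## ISO-8601 on disk and all intervals are closed on both ends.

.SCHEMAS <- list(
  registry = c("person_id", "sex", "birth_date", "death_date",
               "municipality_id", "residency_start", "residency_end"),
  prescriptions = c("person_id", "dispense_date", "atc_code"),
  discharges = c("person_id", "admission_date", "discharge_date",
                 paste0("dx", 1:6)),
  exemptions = c("person_id", "exemption_code", "start_date")
)

#' Keyed pseudonymization of raw identifiers
#'
#' Maps raw identifiers (e.g. social security numbers) to opaque pseudo-IDs
#' with a keyed one-way digest (HMAC-SHA256 truncated to 16 hex characters).
#' The same `(raw_id, secret_key)` pair always yields the same pseudo-ID;
#' without the key the mapping cannot be inverted or recomputed, which is the
#' irreversibility property record linkage across the four databases needs.
#'
#' @param raw_id character vector of raw identifiers; must be non-empty
#'   strings.
#' @param secret_key single string, the linkage key; fixed for a run so all
#'   four sources map consistently.
#' @return character vector of 16-hex-character pseudo-IDs.
#' @examples
#' pseudonymize(c("RSSMRA50A01H501X", "VRDGPP45T10A271K"), "run-key")
#' @export
pseudonymize <- function(raw_id, secret_key) {
  if (!is.character(raw_id) || any(is.na(raw_id)) || any(!nzchar(raw_id)))
    stop("raw_id must be non-empty strings")
  if (!is.character(secret_key) || length(secret_key) != 1L ||
      !nzchar(secret_key))
    stop("secret_key must be a single non-empty string")
  vapply(raw_id,
         function(x) substr(openssl::sha256(x, key = secret_key), 1L, 16L),
         character(1L), USE.NAMES = FALSE)
}

.parse_date <- function(x) as.Date(x, format = "%Y-%m-%d")

## Row-level validation; returns logical keep-vector and reasons for rejects.
.validate_rows <- function(dt, source_kind) {
  n <- nrow(dt)
  bad <- character(0)
  keep <- rep(TRUE, n)
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    if (any(cond)) {
      keep[cond] <<- FALSE
      bad <<- c(bad, sprintf("%s (%d rows)", why, sum(cond)))
    }
  }
  if (source_kind == "registry") {
    flag(!nzchar(dt$person_id) | is.na(dt$person_id), "empty person_id")
    flag(!(dt$sex %in% c("male", "female")), "invalid sex")
    flag(is.na(dt$birth_date), "unparseable birth_date")
    flag(!is.na(dt$death_date) & dt$death_date <= dt$birth_date,
         "death_date <= birth_date")
    flag(!is.na(dt$residency_end) & !is.na(dt$residency_start) &
           dt$residency_end < dt$residency_start,
         "residency interval reversed")
    flag(duplicated(dt$person_id), "duplicate person_id")
  } else if (source_kind == "prescriptions") {
    flag(is.na(dt$dispense_date), "unparseable dispense_date")
    flag(is.na(dt$atc_code) | !grepl("^[A-Z0-9]+$", dt$atc_code),
         "invalid atc_code")
  } else if (source_kind == "discharges") {
    flag(is.na(dt$admission_date) | is.na(dt$discharge_date),
         "unparseable admission/discharge date")
    flag(!is.na(dt$admission_date) & !is.na(dt$discharge_date) &
           dt$admission_date > dt$discharge_date,
         "admission after discharge")
    ndx <- rowSums(!is.na(dt[, paste0("dx", 1:6), with = FALSE]) &
                     dt[, paste0("dx", 1:6), with = FALSE] != "")
    flag(ndx < 1, "no diagnosis code")
  } else if (source_kind == "exemptions") {
    flag(is.na(dt$start_date), "unparseable start_date")
    flag(is.na(dt$exemption_code) | !nzchar(dt$exemption_code),
         "empty exemption_code")
  }
  list(keep = keep, reasons = bad)
}

#' Read one administrative source from CSV
#'
#' Reads and type-checks one of the four sources.  The header must match the
#' documented schema exactly (see Details).  Rows violating record
#' invariants (unparseable dates, more than six diagnoses, reversed
#' intervals, duplicate registry IDs, ...) are rejected, not fatal: the
#' returned table carries a `load_report` attribute with the number read,
#' kept and rejected and the rejection reasons, because real administrative
#' extracts are known-dirty.
#'
#' @details CSV headers: `registry.csv`
#'   `person_id,sex,birth_date,death_date,municipality_id,residency_start,residency_end`;
#'   `prescriptions.csv` `person_id,dispense_date,atc_code`;
#'   `discharges.csv` `person_id,admission_date,discharge_date,dx1..dx6`;
#'   `exemptions.csv` `person_id,exemption_code,start_date`.  A seventh
#'   filled diagnosis column is a schema error.  Dates are ISO-8601; empty
#'   strings are missing.
#'
#' @param path CSV file path.
#' @param source_kind one of `"registry"`, `"prescriptions"`,
#'   `"discharges"`, `"exemptions"`.
#' @return data.table of typed records with attribute `load_report`.
#' @export
read_source <- function(path,
                        source_kind = c("registry", "prescriptions",
                                        "discharges", "exemptions")) {
  source_kind <- match.arg(source_kind)
  cols <- .SCHEMAS[[source_kind]]
  dt <- data.table::fread(path, colClasses = "character", sep = ",",
                          header = TRUE, na.strings = c("", "NA"))
  if (!all(cols %in% names(dt)))
    stop(sprintf("schema error in %s: missing column(s) %s", path,
                 paste(setdiff(cols, names(dt)), collapse = ", ")))
  extra <- setdiff(names(dt), cols)
  if (length(extra))
    stop(sprintf("schema error in %s: unexpected column(s) %s", path,
                 paste(extra, collapse = ", ")))
  n_read <- nrow(dt)
  date_cols <- intersect(cols, c("birth_date", "death_date",
                                 "residency_start", "residency_end",
                                 "dispense_date", "admission_date",
                                 "discharge_date", "start_date"))
  for (dc in date_cols) data.table::set(dt, j = dc,
                                        value = .parse_date(dt[[dc]]))
  v <- .validate_rows(dt, source_kind)
  out <- dt[v$keep]
  data.table::setattr(out, "load_report",
                      list(source_kind = source_kind, n_read = n_read,
                           n_kept = nrow(out),
                           n_rejected = n_read - nrow(out),
                           reasons = v$reasons))
  out[]
}

#' Write one administrative source to CSV
#'
#' Inverse of [read_source()]: writes the documented header and ISO-8601
#' dates so that a read/write round trip is value-identical.
#'
#' @param x records as returned by [read_source()] or the synthetic
#'   generator.
#' @param path output CSV path.
#' @param source_kind which schema to enforce.
#' @return `path`, invisibly.
#' @export
write_source <- function(x, path,
                         source_kind = c("registry", "prescriptions",
                                         "discharges", "exemptions")) {
  source_kind <- match.arg(source_kind)
  cols <- .SCHEMAS[[source_kind]]
  if (!all(cols %in% names(x)))
    stop("missing column(s): ", paste(setdiff(cols, names(x)), collapse = ", "))
  data.table::fwrite(as.data.table(x)[, cols, with = FALSE], path,
                     dateTimeAs = "ISO", na = "", quote = FALSE)
  invisible(path)
}

#' Assemble per-person event histories (record linkage)
#'
#' Links the three event sources to the registry by pseudo-ID.  Every
#' registry person gets a (possibly empty) history; events whose person_id
#' is absent from the registry ("orphans") are dropped with a warning and
#' counted — they are reported, not fatal.  Event tables are sorted by
#' person and date, so downstream criteria can assume chronological order.
#'
#' @param registry,prescriptions,discharges,exemptions tables as returned by
#'   [read_source()]; all pseudonymized with the same key.
#' @return object of class `event_db`: a list with the four sorted tables
#'   and an `orphans` count per event source.
#' @export
build_histories <- function(registry, prescriptions, discharges, exemptions) {
  registry <- as.data.table(registry)
  if (anyDuplicated(registry$person_id))
    stop("registry person_id not unique")
  ids <- registry$person_id
  link <- function(x, date_col) {
    x <- as.data.table(x)
    orphan <- !(x$person_id %in% ids)
    x <- x[!orphan]
    data.table::setorderv(x, c("person_id", date_col))
    list(dt = x, n_orphan = sum(orphan))
  }
  rx <- link(prescriptions, "dispense_date")
  hdr <- link(discharges, "admission_date")
  ex <- link(exemptions, "start_date")
  orphans <- c(prescriptions = rx$n_orphan, discharges = hdr$n_orphan,
               exemptions = ex$n_orphan)
  if (sum(orphans) > 0)
    warning(sprintf("%d orphan event(s) dropped (person_id not in registry)",
                    sum(orphans)))
  data.table::setkey(registry, person_id)
  data.table::setkey(rx$dt, person_id)
  data.table::setkey(hdr$dt, person_id)
  data.table::setkey(ex$dt, person_id)
  structure(list(registry = registry, prescriptions = rx$dt,
                 discharges = hdr$dt, exemptions = ex$dt,
                 orphans = orphans),
            class = "event_db")
}

#' @export
print.event_db <- function(x, ...) {
  cat("Linked administrative event database\n")
  cat(sprintf("  persons:       %d\n", nrow(x$registry)))
  cat(sprintf("  prescriptions: %d\n", nrow(x$prescriptions)))
  cat(sprintf("  discharges:    %d\n", nrow(x$discharges)))
  cat(sprintf("  exemptions:    %d\n", nrow(x$exemptions)))
  if (sum(x$orphans) > 0)
    cat(sprintf("  orphans dropped: %s\n",
                paste(sprintf("%s=%d", names(x$orphans), x$orphans),
                      collapse = ", ")))
  invisible(x)
}

#' Extract one person's event history
#'
#' @param db an `event_db` from [build_histories()].
#' @param id a person_id present in the registry.
#' @return object of class `event_history`: list with `person` (one registry
#'   row) and the person's `prescriptions`, `discharges`, `exemptions`,
#'   each date-sorted.
#' @export
person_history <- function(db, id) {
  stopifnot(inherits(db, "event_db"))
  p <- db$registry[person_id == id]
  if (nrow(p) == 0L) stop("person_id not in registry: ", id)
  structure(list(person = p,
                 prescriptions = db$prescriptions[person_id == id],
                 discharges = db$discharges[person_id == id],
                 exemptions = db$exemptions[person_id == id]),
            class = "event_history")
}

## Build an event_db containing a single person's history (used so the
## single-person classifiers share the vectorized code path).
.history_as_db <- function(history) {
  stopifnot(inherits(history, "event_history"))
  structure(list(registry = history$person,
                 prescriptions = history$prescriptions,
                 discharges = history$discharges,
                 exemptions = history$exemptions,
                 orphans = c(prescriptions = 0L, discharges = 0L,
                             exemptions = 0L)),
            class = "event_db")
}
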