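## Municipality-level counts and rates for disease mapping.  No spatial
## smoothing or small-area shrinkage: raw municipal rates are mapped, so
## small-denominator municipalities are unstable — see the vignette note.

#' Municipality-level case counts, prevalence and incidence
#'
#' Aggregates the identified cohort by municipality of residence for the
#' three analysis groups, with per-1,000 rates over the municipal resident
#' population at the reference date.  Municipal case counts sum to the
#' regional totals by construction.
#'
#' @param cohort a `case_cohort` from [identify_cohort()].
#' @param registry the registry table.
#' @param reference_year must match the cohort's reference year.
#' @return data.table: `municipality_id`, `group`, `population`, `cases`,
#'   `prevalence`, `new_cases`, `incidence` (rates per 1,000), long over
#'   the three groups (inclusive component groups `parkinsonism` and
#'   `dementia`, plus `both`).
#' @export
municipal_rates <- function(cohort, registry,
                            reference_year = cohort$reference_year) {
  stopifnot(inherits(cohort, "case_cohort"))
  if (reference_year != cohort$reference_year)
    stop("reference_year does not match the cohort")
  reg <- as.data.table(registry)
  as_of <- as.Date(sprintf("%d-12-31", reference_year))
  reg <- reg[(is.na(death_date) | death_date >= as_of) &
               (is.na(residency_start) | residency_start <= as_of) &
               (is.na(residency_end) | residency_end >= as_of)]
  reg <- reg[age_at(birth_date, as_of) >= 40]
  pop <- reg[, .(population = .N), by = municipality_id]
  zero <- setdiff(unique(as.data.table(registry)$municipality_id),
                  pop$municipality_id)
  if (length(zero))
    warning("municipalities with zero resident population excluded: ",
            paste(zero, collapse = ", "))

  cases <- cohort$cases
  cm <- reg[, .(person_id, municipality_id)][cases, on = "person_id"]
  if (anyNA(cm$municipality_id))
    stop("case(s) with unknown municipality: ",
         paste(head(cm[is.na(municipality_id), person_id], 5),
               collapse = ", "))
  out <- data.table::rbindlist(lapply(
    c("parkinsonism", "dementia", "both"), function(g) {
      sub <- if (g == "both") cm[group == "both"]
             else cm[group == g | group == "both"]
      agg <- sub[, .(cases = .N, new_cases = sum(incident)),
                 by = municipality_id]
      m <- agg[pop, on = "municipality_id"]
      m[is.na(cases), `:=`(cases = 0L, new_cases = 0L)]
      m[, `:=`(group = g,
               prevalence = 1000 * cases / population,
               incidence = 1000 * new_cases / population)]
      m
    }))
  data.table::setcolorder(out, c("municipality_id", "group", "population",
                                 "cases", "prevalence", "new_cases",
                                 "incidence"))
  data.table::setorder(out, group, municipality_id)
  out[]
}

#' Export municipal rates as GeoJSON or CSV
#'
#' With a geometry file (a GeoJSON FeatureCollection whose features carry a
#' `municipality_id` property), writes an RFC 7946 FeatureCollection with
#' the rate fields attached as properties, one feature per municipality and
#' group.  Without geometry, falls back to a plain CSV.  Municipalities in
#' the rate table with no matching polygon are an error naming exactly the
#' missing IDs.
#'
#' @param rates output of [municipal_rates()].
#' @param path output file path (`.geojson` or `.csv`).
#' @param geometry_file optional GeoJSON path keyed by `municipality_id`.
#' @return `path`, invisibly.
#' @export
export_geojson <- function(rates, path, geometry_file = NULL) {
  rates <- as.data.table(rates)
  if (is.null(geometry_file)) {
    data.table::fwrite(rates, path, quote = FALSE)
    return(invisible(path))
  }
  gj <- jsonlite::read_json(geometry_file)
  if (is.null(gj$features))
    stop("geometry file is not a GeoJSON FeatureCollection")
  geom_ids <- vapply(gj$features,
                     function(f) f$properties$municipality_id %||% NA_character_,
                     character(1))
  missing_ids <- setdiff(unique(rates$municipality_id), geom_ids)
  if (length(missing_ids))
    stop("no geometry for municipality id(s): ",
         paste(missing_ids, collapse = ", "))
  features <- list()
  for (i in seq_len(nrow(rates))) {
    r <- rates[i]
    g <- gj$features[[match(r$municipality_id, geom_ids)]]
    features[[length(features) + 1L]] <- list(
      type = "Feature",
      geometry = g$geometry,
      properties = list(municipality_id = r$municipality_id,
                        group = r$group,
                        population = r$population,
                        cases = r$cases,
                        prevalence = r$prevalence,
                        new_cases = r$new_cases,
                        incidence = r$incidence))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
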