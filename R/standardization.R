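#' Reference age-specific rates from pooled data
#'
#' Divides pooled event counts by pooled person-years within each age group:
#' `rate_g = sum_i O_{i,g} / sum_i PY_{i,g}`. When the inputs are the study
#' data themselves this yields internally standardized rates, under which
#' expected counts reproduce the observed total exactly.
#'
#' @param national_events An `event_table` with age-group breakdown.
#' @param national_population A `population_table` on the same schema.
#' @return A `reference_rates` object (events per person-year).
#' @export
reference_rates <- function(national_events, national_population) {
  stopifnot(inherits(national_events, "event_table"),
            inherits(national_population, "population_table"))
  if (!is.matrix(national_events$counts)) {
    stop("`national_events` must carry an age-group breakdown", call. = FALSE)
  }
  if (!schemas_match(national_events$schema, national_population$schema)) {
    stop("events and population use different age schemas", call. = FALSE)
  }
  ev <- colSums(national_events$counts)
  py <- colSums(person_years(national_population))
  if (any(ev > 0 & py == 0)) {
    bad <- names(ev)[ev > 0 & py == 0]
    stop("events recorded in age group(s) with zero person-years: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rates <- ifelse(py > 0, ev / py, 0)
  reference_rates_table(rates, national_events$schema)
}

#' Expected counts by indirect standardization
#'
#' Applies reference age-specific rates to each area's person-years:
#' `E_i = sum_g rate_g * pop_{i,g} * period_years`. `E_i` is the number of
#' events area `i` would record if it experienced the reference rates.
#'
#' @param rates A `reference_rates` object.
#' @param population A `population_table` on the same schema.
#' @return Named numeric vector of expected counts, class `expected_counts`.
#' @export
expected_counts <- function(rates, population) {
  stopifnot(inherits(rates, "reference_rates"),
            inherits(population, "population_table"))
  if (!schemas_match(rates$schema, population$schema)) {
    stop("rates and population use different age schemas", call. = FALSE)
  }
  e <- as.numeric(person_years(population) %*% rates$rates)
  names(e) <- population$area_ids
  structure(e, class = "expected_counts")
}

#' @export
print.expected_counts <- function(x, ...) {
  cat("<expected_counts> ", length(x), " areas, total E = ",
      format(sum(x)), "\n", sep = "")
  invisible(x)
}

#' Standardized mortality/incidence ratios
#'
#' `SMR_i = O_i / E_i`, the raw (unsmoothed) area relative risk. Areas with
#' `E = 0` and `O = 0` have an undefined ratio and are flagged, not dropped;
#' a positive observed count with zero expected signals corrupt inputs and
#' is an error.
#'
#' @param events An `event_table`.
#' @param expected An `expected_counts` vector aligned to the same areas.
#' @return A data.frame with columns `area_id`, `observed`, `expected`,
#'   `smr`, `undefined`.
#' @export
smr <- function(events, expected) {
  stopifnot(inherits(events, "event_table"))
  o <- event_totals(events)
  if (length(expected) != length(o) ||
      !identical(names(expected), events$area_ids)) {
    stop("expected counts are not aligned to the event-table areas",
         call. = FALSE)
  }
  e <- as.numeric(expected)
  if (any(e == 0 & o > 0)) {
    bad <- events$area_ids[e == 0 & o > 0]
    stop("positive observed count with zero expected in area(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  undefined <- e == 0
  ratio <- ifelse(undefined, NA_real_, o / e)
  data.frame(area_id = events$area_ids, observed = unname(o),
             expected = e, smr = ratio, undefined = undefined,
             stringsAsFactors = FALSE)
}

#' Expand sampled admission records with survey weights
#'
#' Hospital-morbidity surveys ship one row per sampled discharge record
#' together with an expansion weight ("elevation factor") converting it to
#' population-level counts. Weighted counts per area and age group are the
#' sums of the weights of matching records.
#'
#' @param records Data.frame with columns `area_id`, `age_group` (schema
#'   labels) and `weight` (strictly positive).
#' @param schema An `age_schema`.
#' @param area_ids Optional full area set; areas without records get zero.
#' @return A matrix of weighted counts, areas x age groups, with class
#'   attribute `weighted_admissions`.
#' @export
apply_elevation_factors <- function(records, schema, area_ids = NULL) {
  stopifnot(inherits(schema, "age_schema"), is.data.frame(records))
  need <- c("area_id", "age_group", "weight")
  if (!all(need %in% names(records))) {
    stop("`records` must have columns area_id, age_group, weight",
         call. = FALSE)
  }
  if (any(is.na(records$weight)) || any(records$weight <= 0)) {
    stop("elevation factors must be strictly positive", call. = FALSE)
  }
  if (!all(records$age_group %in% schema$labels)) {
    bad <- setdiff(unique(records$age_group), schema$labels)
    stop("age group(s) not in schema: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(c(area_ids, records$area_id))
  w <- matrix(0, nrow = length(ids), ncol = n_groups(schema),
              dimnames = list(ids, schema$labels))
  if (nrow(records)) {
    agg <- stats::aggregate(weight ~ area_id + age_group, data = records, sum)
    w[cbind(agg$area_id, agg$age_group)] <- agg$weight
  }
  structure(w, class = c("weighted_admissions", class(w)))
}

#' Standard population weights for direct standardization
#'
#' @param weights Non-negative weights, one per schema group; normalized to
#'   sum to 1.
#' @param schema An `age_schema`.
#' @return A `standard_population` object.
#' @export
standard_population <- function(weights, schema) {
  stopifnot(inherits(schema, "age_schema"))
  weights <- as.numeric(weights)
  if (length(weights) != n_groups(schema)) {
    stop("one weight per age group required", call. = FALSE)
  }
  if (anyNA(weights) || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum", call. = FALSE)
  }
  structure(list(weights = weights / sum(weights), schema = schema),
            class = "standard_population")
}

#' @rdname standard_population
#' @param population A `population_table` whose pooled age distribution
#'   becomes the standard.
#' @export
pooled_standard <- function(population) {
  stopifnot(inherits(population, "population_table"))
  standard_population(colSums(population$counts), population$schema)
}

#' Directly age-standardized rates
#'
#' `ASR_i = sum_g w_g * events_{i,g} / PY_{i,g}` with standard weights `w`
#' summing to 1. Groups with zero person-years and zero events contribute
#' zero; events in a zero-person-year group are an inconsistency error.
#'
#' @param area_events An `event_table` with ages, or a `weighted_admissions`
#'   matrix.
#' @param population A `population_table` on the same areas and schema.
#' @param standard A `standard_population`.
#' @return Named numeric vector of age-standardized rates per person-year.
#' @export
direct_standardized_rate <- function(area_events, population, standard) {
  stopifnot(inherits(population, "population_table"),
            inherits(standard, "standard_population"))
  if (inherits(area_events, "event_table")) {
    if (!is.matrix(area_events$counts)) {
      stop("`area_events` must carry an age-group breakdown", call. = FALSE)
    }
    ev <- area_events$counts
  } else {
    ev <- unclass(area_events)
  }
  ev <- ev[population$area_ids, standard$schema$labels, drop = FALSE]
  py <- person_years(population)
  if (any(ev > 0 & py == 0)) {
    stop("events recorded in strata with zero person-years", call. = FALSE)
  }
  grate <- ifelse(py > 0, ev / py, 0)
  asr <- as.numeric(grate %*% standard$weights)
  names(asr) <- population$area_ids
  asr
}

#' Rate ratios against a reference rate
#'
#' `ratio_i = ASR_i / ASR_ref`, where the reference is typically the pooled
#' national table standardized with the same standard population (so the
#' pooled data against itself gives exactly 1).
#'
#' @param area_rates Numeric vector of age-standardized rates.
#' @param reference_rate Positive scalar reference rate.
#' @return Numeric vector of rate ratios, names preserved.
#' @export
rate_ratio <- function(area_rates, reference_rate) {
  if (!is.numeric(reference_rate) || length(reference_rate) != 1L ||
      is.na(reference_rate) || reference_rate <= 0) {
    stop("`reference_rate` must be a positive scalar", call. = FALSE)
  }
  area_rates / reference_rate
}

#' Indirectly standardized admission ratios
#'
#' SIR-style alternative to [direct_standardized_rate()]: expected
#' admissions per area under pooled reference rates, with the ratio of
#' observed to expected as the comparable measure.
#'
#' @inheritParams direct_standardized_rate
#' @return Data.frame with columns `area_id`, `observed`, `expected`, `sir`.
#' @export
indirect_standardized_ratio <- function(area_events, population) {
  stopifnot(inherits(population, "population_table"))
  if (inherits(area_events, "event_table")) {
    ev_mat <- area_events$counts
  } else {
    ev_mat <- unclass(area_events)
  }
  ev_mat <- ev_mat[population$area_ids, , drop = FALSE]
  py <- person_years(population)
  pooled_rate <- ifelse(colSums(py) > 0, colSums(ev_mat) / colSums(py), 0)
  e <- as.numeric(py %*% pooled_rate)
  o <- rowSums(ev_mat)
  data.frame(area_id = population$area_ids, observed = unname(o),
             expected = e, sir = ifelse(e > 0, o / e, NA_real_),
             stringsAsFactors = FALSE)
}
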