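#' Event table: observed deaths or admissions by area
#'
#' Observed event counts per area, optionally broken down by age group.
#' Counts must be non-negative integers; an area with no recorded events
#' carries an explicit zero (registry semantics: absence of a record is a
#' count of zero, not missing data).
#'
#' @param area_ids Character vector of unique area identifiers.
#' @param counts Either a numeric vector of per-area totals or a matrix with
#'   one row per area and one column per age group.
#' @param schema An `age_schema`, required when `counts` is a matrix.
#' @param event_kind `"death"` or `"admission"`.
#' @return An object of class `event_table`.
#' @examples
#' ev <- event_table(c("A", "B"), c(3, 0))
#' event_totals(ev)
#' @export
event_table <- function(area_ids, counts, schema = NULL,
                        event_kind = c("death", "admission")) {
  event_kind <- match.arg(event_kind)
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) {
    stop("duplicate area ids: ",
         paste(unique(area_ids[duplicated(area_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.matrix(counts)) {
    if (is.null(schema)) {
      stop("a schema is required for age-stratified counts", call. = FALSE)
    }
    stopifnot(inherits(schema, "age_schema"))
    if (nrow(counts) != length(area_ids) || ncol(counts) != n_groups(schema)) {
      stop("count matrix must be n_areas x n_groups", call. = FALSE)
    }
    dimnames(counts) <- list(area_ids, schema$labels)
  } else {
    counts <- as.numeric(counts)
    if (length(counts) != length(area_ids)) {
      stop("one count per area required", call. = FALSE)
    }
    names(counts) <- area_ids
  }
  check_counts_integer(counts)
  structure(list(area_ids = area_ids, counts = counts, schema = schema,
                 event_kind = event_kind),
            class = "event_table")
}

check_counts_integer <- function(counts) {
  if (anyNA(counts)) stop("event counts must not be missing", call. = FALSE)
  if (any(counts < 0)) {
    stop("event counts must be non-negative", call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("event counts must be integers", call. = FALSE)
  }
  invisible(counts)
}

#' @rdname event_table
#' @param x An `event_table`.
#' @return `event_totals()`: named numeric vector of per-area totals.
#' @export
event_totals <- function(x) {
  stopifnot(inherits(x, "event_table"))
  if (is.matrix(x$counts)) rowSums(x$counts) else x$counts
}

#' @export
print.event_table <- function(x, ...) {
  cat("<event_table> ", length(x$area_ids), " areas, kind=", x$event_kind,
      if (is.matrix(x$counts)) paste0(", ", ncol(x$counts), " age groups"),
      ", total events=", sum(event_totals(x)), "\n", sep = "")
  invisible(x)
}

#' Population table: persons at risk by area and age group
#'
#' Mid-period population counts per area and age group, together with the
#' number of calendar years the study period covers. Person-years are the
#' product of the two: a town of 1,000 men observed for 5 years contributes
#' 5,000 person-years.
#'
#' @param area_ids Character vector of unique area identifiers.
#' @param counts Matrix of non-negative person counts, one row per area and
#'   one column per age group.
#' @param schema An `age_schema` matching the columns of `counts`.
#' @param period_years Positive number of calendar years covered.
#' @return An object of class `population_table`.
#' @examples
#' s <- age_schema("all", 0)
#' p <- population_table("A", matrix(1000), s, period_years = 5)
#' person_years(p)  # 5000
#' @export
population_table <- function(area_ids, counts, schema, period_years) {
  stopifnot(inherits(schema, "age_schema"))
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) {
    stop("duplicate area ids: ",
         paste(unique(area_ids[duplicated(area_ids)]), collapse = ", "),
         call. = FALSE)
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != length(area_ids) || ncol(counts) != n_groups(schema)) {
    stop("count matrix must be n_areas x n_groups", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("population counts must be non-negative", call. = FALSE)
  }
  if (!is.numeric(period_years) || length(period_years) != 1L ||
      is.na(period_years) || period_years <= 0) {
    stop("`period_years` must be a positive number", call. = FALSE)
  }
  dimnames(counts) <- list(area_ids, schema$labels)
  structure(list(area_ids = area_ids, counts = counts, schema = schema,
                 period_years = as.numeric(period_years)),
            class = "population_table")
}

#' @rdname population_table
#' @param x A `population_table`.
#' @return `person_years()`: matrix of person-years (counts times
#'   `period_years`), same shape as `counts`.
#' @export
person_years <- function(x) {
  stopifnot(inherits(x, "population_table"))
  x$counts * x$period_years
}

#' @export
print.population_table <- function(x, ...) {
  cat("<population_table> ", length(x$area_ids), " areas x ",
      ncol(x$counts), " age groups, period ", x$period_years,
      " y, total person-years ", format(sum(person_years(x))), "\n", sep = "")
  invisible(x)
}

#' Reference age-specific rates
#'
#' National (or other reference) event rates per person-year, one per age
#' group. These drive indirect standardization: applied to an area's age
#' structure they yield the events the area would see at reference risk.
#'
#' @param rates Non-negative numeric vector, one rate per schema group,
#'   in events per person-year.
#' @param schema The `age_schema` the rates are stratified on.
#' @return An object of class `reference_rates`.
#' @export
reference_rates_table <- function(rates, schema) {
  stopifnot(inherits(schema, "age_schema"))
  rates <- as.numeric(rates)
  if (length(rates) != n_groups(schema)) {
    stop("one rate per age group required", call. = FALSE)
  }
  if (anyNA(rates) || any(rates < 0)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  names(rates) <- schema$labels
  structure(list(rates = rates, schema = schema), class = "reference_rates")
}

#' @export
print.reference_rates <- function(x, ...) {
  cat("<reference_rates> ", length(x$rates), " age groups, range [",
      format(min(x$rates), digits = 3), ", ",
      format(max(x$rates), digits = 3), "] per person-year\n", sep = "")
  invisible(x)
}

#' Restrict events and population to an age stratum
#'
#' Truncates both tables to the age groups lying entirely below a cutoff
#' (lower bound < cutoff), e.g. cutoff 65 on the default 18-group schema
#' keeps the 13 groups 0-4 through 60-64. The cutoff must coincide with a
#' group boundary; a cutoff above the top bound returns the tables
#' unchanged. Reference rates for the stratum must be recomputed inside it.
#'
#' @param events An `event_table` with age-group breakdown.
#' @param population A `population_table` on the same schema.
#' @param cutoff_years Integer age cutoff in years.
#' @return A list with elements `events` and `population`, both truncated.
#' @export
restrict_to_age <- function(events, population, cutoff_years) {
  stopifnot(inherits(events, "event_table"),
            inherits(population, "population_table"))
  if (!is.matrix(events$counts) || is.null(events$schema)) {
    stop("`events` must carry an age-group breakdown", call. = FALSE)
  }
  if (!schemas_match(events$schema, population$schema)) {
    stop("events and population use different age schemas", call. = FALSE)
  }
  keep <- groups_below_cutoff(events$schema, cutoff_years)
  if (length(keep) == n_groups(events$schema)) {
    return(list(events = events, population = population))
  }
  sub <- age_schema(events$schema$labels[keep],
                    events$schema$lower_bounds[keep])
  list(
    events = event_table(events$area_ids,
                         events$counts[, keep, drop = FALSE],
                         sub, events$event_kind),
    population = population_table(population$area_ids,
                                  population$counts[, keep, drop = FALSE],
                                  sub, population$period_years)
  )
}
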