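#' Age-group schema
#'
#' An ordered set of age groups, each identified by a label and the lower
#' bound of its age range in years. The last group is open-ended. Registry
#' tables (events, populations, reference rates) are stratified on a schema,
#' and all joins between them require schema agreement.
#'
#' @param labels Character vector of unique group names, ordered by age.
#' @param lower_bounds Integer vector of lower age bounds (years), strictly
#'   increasing, same length as `labels`.
#' @return An object of class `age_schema`.
#' @examples
#' s <- age_schema(c("0-4", "5+"), c(0, 5))
#' n_groups(s)
#' @export
age_schema <- function(labels, lower_bounds) {
  labels <- as.character(labels)
  lower_bounds <- as.integer(lower_bounds)
  if (length(labels) == 0L) {
    stop("age schema must contain at least one group", call. = FALSE)
  }
  if (length(labels) != length(lower_bounds)) {
    stop("`labels` and `lower_bounds` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("age-group labels must be unique", call. = FALSE)
  }
  if (anyNA(lower_bounds) || any(diff(lower_bounds) <= 0L)) {
    stop("`lower_bounds` must be strictly increasing integers", call. = FALSE)
  }
  structure(list(labels = labels, lower_bounds = lower_bounds),
            class = "age_schema")
}

#' Default 18-group quinquennial schema
#'
#' Five-year age groups 0-4, 5-9, ..., 80-84, 85+ — the stratification used
#' by national statistical institutes for municipal population rolls. The
#' exact boundaries of registry age groupings vary between sources, so every
#' reader accepts an explicit schema; this default is an assumption, not a
#' registry fact.
#'
#' @return An `age_schema` with 18 groups.
#' @export
default_age_schema <- function() {
  lb <- seq(0L, 85L, by = 5L)
  labels <- c(paste(lb[-18L], lb[-18L] + 4L, sep = "-"), "85+")
  age_schema(labels, lb)
}

#' @rdname age_schema
#' @param schema An `age_schema`.
#' @export
n_groups <- function(schema) {
  stopifnot(inherits(schema, "age_schema"))
  length(schema$labels)
}

#' @export
print.age_schema <- function(x, ...) {
  cat("<age_schema> ", length(x$labels), " groups: ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
format.age_schema <- function(x, ...) {
  paste0("age_schema[", length(x$labels), "]")
}

schemas_match <- function(a, b) {
  identical(a$labels, b$labels) && identical(a$lower_bounds, b$lower_bounds)
}

# index of groups entirely below an age cutoff; cutoff must sit on a boundary
groups_below_cutoff <- function(schema, cutoff_years) {
  lb <- schema$lower_bounds
  if (cutoff_years > lb[length(lb)]) {
    return(seq_along(lb))
  }
  if (!cutoff_years %in% lb) {
    below <- max(lb[lb < cutoff_years])
    above <- min(lb[lb > cutoff_years])
    stop(sprintf(
      "age cutoff %d is not a group boundary (nearest boundaries: %d, %d)",
      cutoff_years, below, above), call. = FALSE)
  }
  which(lb < cutoff_years)
}
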