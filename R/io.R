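#' Read an event table from CSV
#'
#' Expects a header row with an `area_id` column (or the first column taken
#' as area ids) and either a single `total` column or one column per age
#' group of `schema`, named by its labels. Missing cells are treated as
#' zero counts and logged; malformed numeric cells are an error naming the
#' offending row and column.
#'
#' @param path Path to a CSV file (UTF-8, header row).
#' @param schema An `age_schema`; required when the file carries per-group
#'   columns.
#' @param event_kind `"death"` or `"admission"`.
#' @return An `event_table`.
#' @export
read_event_table <- function(path, schema = NULL,
                             event_kind = c("death", "admission")) {
  event_kind <- match.arg(event_kind)
  df <- read_registry_csv(path)
  area_ids <- df$area_ids
  body <- df$body
  if (!is.null(schema) && all(schema$labels %in% colnames(body))) {
    counts <- sapply(schema$labels, function(g) {
      parse_count_column(body[[g]], g, path)
    })
    if (length(area_ids) == 1L) counts <- matrix(counts, nrow = 1L)
    ev <- event_table(area_ids, counts, schema, event_kind)
  } else if ("total" %in% colnames(body)) {
    totals <- parse_count_column(body[["total"]], "total", path)
    ev <- event_table(area_ids, totals, event_kind = event_kind)
  } else if (ncol(body) == 1L) {
    totals <- parse_count_column(body[[1L]], colnames(body)[1L], path)
    ev <- event_table(area_ids, totals, event_kind = event_kind)
  } else {
    stop("cannot interpret columns of ", path,
         ": expected a `total` column or one column per age-schema group",
         call. = FALSE)
  }
  message(sprintf("read_event_table: %d areas, %d events from %s",
                  length(area_ids), sum(event_totals(ev)), path))
  ev
}

#' Read a population table from CSV
#'
#' Expects an `area_id` column plus one column per age group of `schema`,
#' named by its labels.
#'
#' @param path Path to a CSV file.
#' @param schema An `age_schema`; every group label must appear as a column.
#' @param period_years Positive number of calendar years the mid-period
#'   population represents (person-years = population x `period_years`).
#' @return A `population_table`.
#' @export
read_population_table <- function(path, schema, period_years) {
  stopifnot(inherits(schema, "age_schema"))
  df <- read_registry_csv(path)
  missing_cols <- setdiff(schema$labels, colnames(df$body))
  if (length(missing_cols)) {
    stop("schema mismatch in ", path, ": missing age columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  counts <- sapply(schema$labels, function(g) {
    parse_count_column(df$body[[g]], g, path, integer_only = FALSE)
  })
  if (length(df$area_ids) == 1L) counts <- matrix(counts, nrow = 1L)
  pop <- population_table(df$area_ids, counts, schema, period_years)
  message(sprintf("read_population_table: %d areas, %s person-years from %s",
                  length(df$area_ids), format(sum(person_years(pop))), path))
  pop
}

# shared CSV ingestion: area id column + body of count columns
read_registry_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty table: ", path, call. = FALSE)
  id_col <- if ("area_id" %in% colnames(df)) "area_id" else colnames(df)[1L]
  area_ids <- as.character(df[[id_col]])
  list(area_ids = area_ids, body = df[setdiff(colnames(df), id_col)])
}

parse_count_column <- function(x, col, path, integer_only = TRUE) {
  blank <- is.na(x) | trimws(x) == ""
  if (any(blank)) {
    message(sprintf("%s: %d missing cell(s) in column '%s' filled with 0",
                    path, sum(blank), col))
    x[blank] <- "0"
  }
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    bad <- which(is.na(v))[1L]
    stop(sprintf("malformed numeric cell in %s: row %d, column '%s' ('%s')",
                 path, bad, col, x[bad]), call. = FALSE)
  }
  v
}

#' Write event or population tables to CSV
#'
#' Inverse of the readers: round-tripping any valid table through
#' `write_*` / `read_*` reproduces it exactly.
#'
#' @param x An `event_table` or `population_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(x, path) {
  stopifnot(inherits(x, "event_table"))
  if (is.matrix(x$counts)) {
    df <- data.frame(area_id = x$area_ids, x$counts, check.names = FALSE)
  } else {
    df <- data.frame(area_id = x$area_ids, total = unname(x$counts))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
write_population_table <- function(x, path) {
  stopifnot(inherits(x, "population_table"))
  df <- data.frame(area_id = x$area_ids, x$counts, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
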