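#' Run the full small-area analysis pipeline
#'
#' Orchestrates read -> standardize -> fit -> summarize -> classify from a
#' single configuration: reads the event, population and adjacency files,
#' computes reference rates from the pooled data (indirect
#' standardization), optionally restricts to an age stratum (recomputing
#' the reference rates inside it), fits the BYM model, classifies risks
#' and writes the result bundle (`smr.csv`, `fit.csv`,
#' `classification.csv`, `map.geojson`, `manifest.json`) to `output_dir`.
#' Re-running from the written manifest reproduces the outputs
#' byte-for-byte.
#'
#' @param config A list, or path to a JSON file, with elements:
#'   `events`, `population`, `adjacency` (paths), `period_years`,
#'   `output_dir`, `seed`, and optionally `age_cutoff`, `schema`
#'   (`labels` + `lower_bounds`), `model` (arguments to [bym_config()]),
#'   `rr_edges`, `pp_edges`.
#' @return Invisibly, a list with `fit`, `smr`, `classification` and the
#'   manifest path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (field in c("events", "population", "adjacency", "period_years",
                  "output_dir", "seed")) {
    if (is.null(config[[field]])) {
      stop("[config] missing required field `", field, "`", call. = FALSE)
    }
  }
  schema <- if (!is.null(config$schema)) {
    age_schema(config$schema$labels, config$schema$lower_bounds)
  } else {
    default_age_schema()
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  events <- stage("read", read_event_table(config$events, schema))
  population <- stage("read", read_population_table(
    config$population, schema, config$period_years))
  graph <- stage("read", read_adjacency(config$adjacency,
                                        area_ids = population$area_ids))

  # areas in the population roll but with no recorded events carry O = 0
  extra <- setdiff(population$area_ids, events$area_ids)
  if (length(extra)) {
    message("[read] ", length(extra),
            " area(s) without event records assigned O = 0")
    events <- stage("read", pad_events(events, extra, schema))
  }
  events <- stage("read", reorder_events(events, population$area_ids))

  if (!is.null(config$age_cutoff)) {
    r <- stage("restrict",
               restrict_to_age(events, population, config$age_cutoff))
    events <- r$events
    population <- r$population
    message("[restrict] kept ", n_groups(events$schema),
            " age groups below ", config$age_cutoff, " years")
  }

  rates <- stage("standardize", reference_rates(events, population))
  expected <- stage("standardize", expected_counts(rates, population))
  smr_tab <- stage("standardize", smr(events, expected))
  message("[standardize] total O = ", sum(smr_tab$observed),
          ", total E = ", format(sum(smr_tab$expected)))

  model_args <- c(config$model, list(seed = config$seed))
  model_args <- model_args[!duplicated(names(model_args))]
  cfg <- stage("fit", do.call(bym_config, model_args))
  fit <- stage("fit", fit_bym(events, expected, graph, cfg))
  message("[fit] ", fit$n_kept, " kept draws, ",
          length(fit$dropped_areas), " area(s) dropped (no population)")

  cls <- stage("classify", classify_risk(fit, rr_edges = config$rr_edges,
                                         pp_edges = config$pp_edges %||%
                                           seq(0.1, 0.9, by = 0.1)))

  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(smr_tab, file.path(out, "smr.csv"), row.names = FALSE)
  utils::write.csv(fit$summary, file.path(out, "fit.csv"), row.names = FALSE)
  utils::write.csv(cls, file.path(out, "classification.csv"),
                   row.names = FALSE)
  stage("report", write_geojson(fit, file.path(out, "map.geojson"),
                                graph = graph, classification = cls))
  manifest <- list(
    package_version = as.character(utils::packageVersion("bymsmooth")),
    seed = config$seed,
    config = config[setdiff(names(config), "output_dir")],
    output_dir = out,
    n_areas = nrow(fit$summary),
    n_dropped = length(fit$dropped_areas),
    acceptance = as.list(fit$acceptance),
    rr_edges = attr(cls, "rr_edges"),
    pp_edges = attr(cls, "pp_edges"))
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  message("[report] bundle written to ", out)
  invisible(list(fit = fit, smr = smr_tab, classification = cls,
                 manifest = manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pad_events <- function(events, extra, schema) {
  if (is.matrix(events$counts)) {
    zeros <- matrix(0, nrow = length(extra), ncol = ncol(events$counts))
    event_table(c(events$area_ids, extra), rbind(events$counts, zeros),
                schema, events$event_kind)
  } else {
    event_table(c(events$area_ids, extra),
                c(events$counts, rep(0, length(extra))),
                event_kind = events$event_kind)
  }
}

reorder_events <- function(events, ids) {
  m <- match(ids, events$area_ids)
  if (anyNA(m)) {
    stop("event area(s) absent from population table: ",
         paste(setdiff(events$area_ids, ids), collapse = ", "),
         call. = FALSE)
  }
  if (is.matrix(events$counts)) {
    event_table(ids, events$counts[m, , drop = FALSE], events$schema,
                events$event_kind)
  } else {
    event_table(ids, events$counts[m], event_kind = events$event_kind)
  }
}

#' Write a synthetic registry bundle to disk
#'
#' Materializes [simulate_registry()] output as the pipeline's input
#' formats: `population.csv`, `events.csv`, `adjacency.gal`, `truth.csv`
#' and `scenario.json`.
#'
#' @param scenario A `synthetic_scenario`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of written paths plus the simulation.
#' @export
write_synthetic_bundle <- function(scenario, dir) {
  sim <- simulate_registry(scenario)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    population = file.path(dir, "population.csv"),
    events = file.path(dir, "events.csv"),
    adjacency = file.path(dir, "adjacency.gal"),
    truth = file.path(dir, "truth.csv"),
    scenario = file.path(dir, "scenario.json"))
  write_population_table(sim$population, paths$population)
  write_event_table(sim$events, paths$events)
  write_gal(sim$graph, paths$adjacency)
  utils::write.csv(
    data.frame(area_id = names(sim$true_rr),
               true_rr = unname(sim$true_rr),
               true_h = unname(sim$true_h), true_b = unname(sim$true_b)),
    paths$truth, row.names = FALSE)
  sc <- sim$scenario
  jsonlite::write_json(
    list(rows = sc$rows, cols = sc$cols,
         schema = list(labels = sc$schema$labels,
                       lower_bounds = sc$schema$lower_bounds),
         pop_median = sc$pop_median, pop_sdlog = sc$pop_sdlog,
         rate_log_slope = sc$rate_log_slope,
         mean_expected = sc$mean_expected, tau_h = sc$tau_h,
         tau_b = sc$tau_b, period_years = sc$period_years,
         seed = sc$seed),
    paths$scenario, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, list(sim = sim)))
}
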