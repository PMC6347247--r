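#' Rook-contiguity lattice graph
#'
#' A rows x cols grid with horizontal and vertical neighbours — the
#' standard stand-in for municipal contiguity in simulation studies. Node
#' ids are `"r<i>c<j>"`.
#'
#' @param rows,cols Positive integers.
#' @return An `adjacency_graph` with attribute-free lattice coordinates
#'   recoverable via [lattice_coords()].
#' @examples
#' make_lattice(2, 2)  # 4 nodes, 4 edges
#' @export
make_lattice <- function(rows, cols) {
  if (rows < 1 || cols < 1) {
    stop("lattice dimensions must be >= 1", call. = FALSE)
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  id <- function(r, c) paste0("r", r, "c", c)
  grid <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  ids <- id(grid$r, grid$c)
  edges <- NULL
  if (cols > 1L) {
    right <- grid[grid$c < cols, ]
    edges <- rbind(edges, cbind(id(right$r, right$c), id(right$r, right$c + 1L)))
  }
  if (rows > 1L) {
    down <- grid[grid$r < rows, ]
    edges <- rbind(edges, cbind(id(down$r, down$c), id(down$r + 1L, down$c)))
  }
  g <- adjacency_graph(ids, edges)
  g$coords <- cbind(row = grid$r, col = grid$c)
  rownames(g$coords) <- ids
  g
}

#' @rdname make_lattice
#' @param graph An `adjacency_graph`.
#' @return `lattice_coords()`: two-column matrix of node coordinates
#'   (lattice position if built by `make_lattice`, otherwise a circular
#'   layout).
#' @export
lattice_coords <- function(graph) {
  if (!is.null(graph$coords)) return(graph$coords)
  n <- length(graph$area_ids)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  out <- cbind(row = sin(theta), col = cos(theta))
  rownames(out) <- graph$area_ids
  out
}

#' Sample from the intrinsic CAR distribution
#'
#' Draws a spatial field with density proportional to
#' `exp(-tau_h/2 * sum_edges (h_i - h_j)^2)` restricted to the sum-to-zero
#' subspace of each connected component. Sampling goes through the
#' eigendecomposition of the graph Laplacian: each positive-eigenvalue
#' direction gets an independent Gaussian with variance
#' `1 / (tau_h * eigenvalue)`; null-space (per-component constant)
#' directions are excluded, so component sums are zero by construction.
#'
#' @param graph An `adjacency_graph`.
#' @param tau_h Positive precision.
#' @return Numeric field named by area id.
#' @export
sample_icar_field <- function(graph, tau_h) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (tau_h <= 0) stop("`tau_h` must be positive", call. = FALSE)
  n <- length(graph$area_ids)
  L <- matrix(0, n, n)
  e <- graph$edges
  for (k in seq_len(nrow(e))) {
    i <- e[k, 1L]; j <- e[k, 2L]
    L[i, j] <- L[i, j] - 1
    L[j, i] <- L[j, i] - 1
    L[i, i] <- L[i, i] + 1
    L[j, j] <- L[j, j] + 1
  }
  eg <- eigen(L, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 1) * 1e-10
  h <- if (any(pos)) {
    z <- stats::rnorm(sum(pos), sd = 1 / sqrt(tau_h * eg$values[pos]))
    as.numeric(eg$vectors[, pos, drop = FALSE] %*% z)
  } else {
    numeric(n)
  }
  # exact per-component recentring (removes eigenvector rounding residue)
  h <- h - stats::ave(h, graph$components)
  names(h) <- graph$area_ids
  h
}

#' Default male age distribution across the 18-group schema
#'
#' Approximate shares of a southern-European national male population by
#' five-year age group, used to split simulated municipal populations into
#' strata. Synthetic: a smooth plausible pyramid, not census data.
#'
#' @return Numeric vector of 18 shares summing to 1.
#' @export
default_age_distribution <- function() {
  w <- c(5.3, 5.5, 5.2, 4.9, 5.3, 6.2, 7.6, 8.6, 8.6, 8.0, 7.2, 6.3,
         5.3, 4.3, 3.6, 3.0, 2.1, 1.0)
  w / sum(w)
}

#' Scenario for the synthetic registry generator
#'
#' Bundles every knob of [simulate_registry()]: a contiguity lattice,
#' log-normal municipal population sizes (small towns to cities, spanning
#' several orders of magnitude), an exponential age-rate curve whose
#' steepness puts about 6% of events below age 65 under the default age
#' pyramid, a latent spatially correlated log-risk field plus unstructured
#' noise, and optional multiplicative hot-spot zones.
#'
#' @param rows,cols Lattice dimensions (ignored when `graph` is given).
#' @param graph Optional explicit `adjacency_graph`.
#' @param schema An `age_schema`; the age distribution and rate curve are
#'   indexed by its groups.
#' @param age_distribution Population shares per age group.
#' @param pop_median,pop_sdlog Log-normal parameters for total area
#'   population (median persons and log-scale spread).
#' @param rate_log_slope Slope of the log baseline rate per age-group
#'   index (events per person-year rise `exp(slope)`-fold per group).
#' @param mean_expected Target mean expected count per area; the baseline
#'   curve is scaled so that the mean of `E_i` under the generating rates
#'   equals it. The default 4 reproduces the sparse-count regime of
#'   national cause-specific mortality at municipal resolution.
#' @param tau_h,tau_b Precisions of the latent spatial (ICAR) and
#'   heterogeneity fields; `Inf` switches a field off.
#' @param hotspots Optional list of `list(nodes =, multiplier =)` entries;
#'   node sets are area ids whose relative risk is multiplied.
#' @param period_years Calendar years covered (person-years multiplier).
#' @param seed Integer seed; generation is deterministic given it.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(rows = 20L, cols = 20L, graph = NULL,
                               schema = default_age_schema(),
                               age_distribution = default_age_distribution(),
                               pop_median = 2000, pop_sdlog = 1.5,
                               rate_log_slope = 0.806, mean_expected = 4,
                               tau_h = 1, tau_b = 10, hotspots = NULL,
                               period_years = 5, seed = 1L) {
  stopifnot(inherits(schema, "age_schema"))
  if (length(age_distribution) != n_groups(schema)) {
    stop("one age-distribution share per schema group required",
         call. = FALSE)
  }
  if (any(age_distribution < 0) || sum(age_distribution) <= 0) {
    stop("age-distribution shares must be non-negative", call. = FALSE)
  }
  if (pop_median <= 0 || pop_sdlog < 0 || mean_expected <= 0 ||
      period_years <= 0) {
    stop("population, expected-count and period parameters must be positive",
         call. = FALSE)
  }
  if (tau_h <= 0 || tau_b <= 0) {
    stop("latent-field precisions must be positive", call. = FALSE)
  }
  for (hs in hotspots) {
    if (is.null(hs$nodes) || is.null(hs$multiplier) || hs$multiplier <= 0) {
      stop("each hotspot needs `nodes` and a positive `multiplier`",
           call. = FALSE)
    }
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 graph = graph, schema = schema,
                 age_distribution = age_distribution / sum(age_distribution),
                 pop_median = pop_median, pop_sdlog = pop_sdlog,
                 rate_log_slope = rate_log_slope,
                 mean_expected = mean_expected, tau_h = tau_h,
                 tau_b = tau_b, hotspots = hotspots,
                 period_years = period_years, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("<synthetic_scenario> ",
      if (is.null(x$graph)) paste0(x$rows, "x", x$cols, " lattice")
      else paste0(length(x$graph$area_ids), "-node graph"),
      ", ", n_groups(x$schema), " age groups, tau_h=", x$tau_h,
      ", tau_b=", x$tau_b, ", mean E=", x$mean_expected,
      ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate a registry-style dataset with known ground truth
#'
#' Generates a full synthetic mortality registry from a
#' [synthetic_scenario()]: age-structured populations, a latent log-risk
#' field `log(RR_i) = h_i + b_i (+ log hot-spot multiplier)`, and event
#' counts `O_{i,g} ~ Poisson(pop_{i,g} * period * rate_g * RR_i)`.
#' Deterministic given the scenario seed.
#'
#' @param scenario A `synthetic_scenario`.
#' @return A list with `population` (`population_table`), `events`
#'   (`event_table` with age breakdown), `graph` (`adjacency_graph`),
#'   `true_rr` (named vector), `true_h`, `true_b`, `rates` (the generating
#'   `reference_rates`), and `scenario`.
#' @export
simulate_registry <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  graph <- scenario$graph
  if (is.null(graph)) graph <- make_lattice(scenario$rows, scenario$cols)
  ids <- graph$area_ids
  n <- length(ids)
  g <- n_groups(scenario$schema)

  pop_tot <- stats::rlnorm(n, meanlog = log(scenario$pop_median),
                           sdlog = scenario$pop_sdlog)
  pop <- round(outer(pop_tot, scenario$age_distribution))
  storage.mode(pop) <- "double"
  population <- population_table(ids, pop, scenario$schema,
                                 scenario$period_years)

  h <- if (is.finite(scenario$tau_h)) {
    sample_icar_field(graph, scenario$tau_h)
  } else {
    stats::setNames(numeric(n), ids)
  }
  b <- stats::setNames(
    if (is.finite(scenario$tau_b)) {
      stats::rnorm(n, sd = 1 / sqrt(scenario$tau_b))
    } else numeric(n), ids)
  log_rr <- h + b
  for (hs in scenario$hotspots) {
    idx <- match(hs$nodes, ids)
    if (anyNA(idx)) {
      stop("hotspot node(s) absent from graph: ",
           paste(hs$nodes[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    log_rr[idx] <- log_rr[idx] + log(hs$multiplier)
  }
  true_rr <- exp(log_rr)

  base_curve <- exp(scenario$rate_log_slope * seq_len(g))
  py <- person_years(population)
  # scale curve so the mean expected count per area hits the target
  scale <- scenario$mean_expected * n / sum(py %*% base_curve)
  rates <- base_curve * scale
  mu <- (py * rep(rates, each = n)) * true_rr
  o <- matrix(stats::rpois(n * g, mu), nrow = n)
  events <- event_table(ids, o, scenario$schema, "death")

  list(population = population, events = events, graph = graph,
       true_rr = true_rr, true_h = h, true_b = b,
       rates = reference_rates_table(rates, scenario$schema),
       scenario = scenario)
}

#' Simulate survey-style admission records with expansion weights
#'
#' Emulates a hospital-morbidity survey: record-level discharges whose
#' expansion weights ("elevation factors") make weighted totals match the
#' scenario's expected admission counts in expectation. With weight `w`
#' per record, the record count in a stratum is Poisson with mean
#' `mu / w`, so the weighted total has mean `mu`.
#'
#' @param scenario A `synthetic_scenario`; admissions reuse its population
#'   and rate structure scaled by `admission_multiplier`.
#' @param weight_model `"constant"` or `"gamma"` (weights drawn from a
#'   Gamma distribution with the given mean).
#' @param mean_weight Mean expansion weight (> 0).
#' @param gamma_shape Shape of the Gamma weight distribution.
#' @param admission_multiplier Ratio of admission to event rates
#'   (hospitalizations are far more frequent than deaths).
#' @return A list with `records` (data.frame `area_id`, `age_group`,
#'   `weight`), `population`, `graph`, `true_rr`, `rates` (admission
#'   rates) and `scenario`.
#' @export
simulate_admissions <- function(scenario,
                                weight_model = c("constant", "gamma"),
                                mean_weight = 20, gamma_shape = 4,
                                admission_multiplier = 10) {
  weight_model <- match.arg(weight_model)
  if (mean_weight <= 0) stop("`mean_weight` must be positive", call. = FALSE)
  reg <- simulate_registry(scenario)
  py <- person_years(reg$population)
  n <- nrow(py)
  rates <- reg$rates$rates * admission_multiplier
  mu <- (py * rep(rates, each = n)) * reg$true_rr
  n_rec <- matrix(stats::rpois(length(mu), mu / mean_weight), nrow = n)
  total <- sum(n_rec)
  ids <- reg$population$area_ids
  labels <- scenario$schema$labels
  rec_area <- rep(rep(ids, times = ncol(py)), as.vector(n_rec))
  rec_age <- rep(rep(labels, each = n), as.vector(n_rec))
  weights <- if (weight_model == "constant") {
    rep(mean_weight, total)
  } else {
    stats::rgamma(total, shape = gamma_shape,
                  rate = gamma_shape / mean_weight)
  }
  list(records = data.frame(area_id = rec_area, age_group = rec_age,
                            weight = weights, stringsAsFactors = FALSE),
       population = reg$population, graph = reg$graph,
       true_rr = reg$true_rr,
       rates = reference_rates_table(rates, scenario$schema),
       scenario = scenario)
}
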