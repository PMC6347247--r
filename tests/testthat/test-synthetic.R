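test_that("rook lattices have the expected nodes, edges and components", {
  g22 <- make_lattice(2, 2)
  expect_equal(length(g22$area_ids), 4L)
  expect_equal(nrow(g22$edges), 4L)
  expect_equal(g22$n_components, 1L)
  expect_equal(nrow(make_lattice(3, 3)$edges), 12L)
  g11 <- make_lattice(1, 1)
  expect_equal(length(g11$area_ids), 1L)
  expect_equal(nrow(g11$edges), 0L)
  expect_error(make_lattice(0, 3), ">= 1")
})

test_that("ICAR field draws are centred per component with the right scale", {
  set.seed(55)
  g <- make_lattice(4, 5)
  for (k in 1:5) {
    h <- sample_icar_field(g, tau_h = 2)
    expect_lt(abs(sum(h)), 1e-10)
  }
  # disconnected graph: both component sums vanish
  gd <- adjacency_graph(c("a", "b", "c", "d"),
                        rbind(c("a", "b"), c("c", "d")))
  h <- sample_icar_field(gd, 1)
  expect_lt(abs(h["a"] + h["b"]), 1e-10)
  expect_lt(abs(h["c"] + h["d"]), 1e-10)

  # 2-node path: the single positive Laplacian eigenvalue (2) gives
  # Var(h1 - h2) = 1/tau on the constrained subspace
  g2 <- adjacency_graph(c("a", "b"), cbind("a", "b"))
  tau <- 4
  set.seed(56)
  d <- replicate(2e4, { h <- sample_icar_field(g2, tau); h[1] - h[2] })
  target <- 1 / tau
  se <- target * sqrt(2 / length(d))
  expect_lt(abs(var(d) - target), 3 * se)
})

test_that("the empirical ICAR pairwise sum scales as (n - c)/tau", {
  set.seed(57)
  g <- make_lattice(3, 4)
  tau <- 2.5
  s <- replicate(3e3, icar_pairwise_sum(sample_icar_field(g, tau), g))
  # E[S] = (n - c)/tau by the trace identity on the constrained Gaussian
  target <- (length(g$area_ids) - g$n_components) / tau
  expect_lt(abs(mean(s) - target) / target, 0.1)
})

test_that("simulate_registry is deterministic and honours the null scenario", {
  sc <- synthetic_scenario(rows = 5, cols = 5, tau_h = Inf, tau_b = Inf,
                           mean_expected = 20, seed = 12)
  a <- simulate_registry(sc)
  b <- simulate_registry(sc)
  expect_identical(a$events$counts, b$events$counts)
  expect_identical(a$population$counts, b$population$counts)
  expect_true(all(a$true_rr == 1))
  # null scenario: total observed tracks total expected within Poisson error
  e <- expected_counts(a$rates, a$population)
  tot_e <- sum(e)
  expect_lt(abs(sum(event_totals(a$events)) - tot_e), 4 * sqrt(tot_e))
})

test_that("generated registries pass input validation cleanly", {
  sc <- synthetic_scenario(rows = 4, cols = 4, seed = 3)
  sim <- simulate_registry(sc)
  expect_silent_messages({
    ev <- event_table(sim$events$area_ids, sim$events$counts,
                      sim$events$schema)
    pop <- population_table(sim$population$area_ids, sim$population$counts,
                            sim$population$schema,
                            sim$population$period_years)
    g <- adjacency_graph(sim$graph$area_ids,
                         cbind(sim$graph$area_ids[sim$graph$edges[, 1]],
                               sim$graph$area_ids[sim$graph$edges[, 2]]))
  })
  # ~6% of events fall under 65 at the default rate curve (composition
  # check at generous tolerance; it is a scenario default, not a target)
  sc_big <- synthetic_scenario(rows = 8, cols = 8, pop_median = 5e4,
                               pop_sdlog = 0.5, mean_expected = 200,
                               tau_h = Inf, tau_b = Inf, seed = 14)
  sim_big <- simulate_registry(sc_big)
  under <- which(sc_big$schema$lower_bounds < 65)
  frac <- sum(sim_big$events$counts[, under]) /
    sum(sim_big$events$counts)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.12)
})

test_that("injected hot spots surface in empirical SMRs at large populations", {
  g <- make_lattice(4, 4)
  block <- c("r1c1", "r1c2", "r2c1", "r2c2")
  sc <- synthetic_scenario(graph = g, pop_median = 1e6, pop_sdlog = 0,
                           mean_expected = 2000, tau_h = Inf, tau_b = Inf,
                           hotspots = list(list(nodes = block,
                                                multiplier = 2)),
                           seed = 15)
  sim <- simulate_registry(sc)
  e <- expected_counts(sim$rates, sim$population)  # generating rates
  ratio <- event_totals(sim$events) / e
  expect_equal(unname(mean(ratio[block])), 2, tolerance = 0.05)
  outside <- setdiff(names(ratio), block)
  expect_equal(unname(mean(ratio[outside])), 1, tolerance = 0.05)
})

test_that("simulated admissions respect the survey-weight design", {
  sc <- synthetic_scenario(rows = 3, cols = 3, pop_median = 5e4,
                           pop_sdlog = 0.3, mean_expected = 50,
                           tau_h = Inf, tau_b = Inf, seed = 16)
  adm1 <- simulate_admissions(sc, weight_model = "constant",
                              mean_weight = 1)
  w1 <- apply_elevation_factors(adm1$records, sc$schema,
                                area_ids = adm1$population$area_ids)
  expect_equal(sum(w1), nrow(adm1$records))

  # halving record counts by doubling the weight keeps the weighted total
  adm2 <- simulate_admissions(sc, weight_model = "constant",
                              mean_weight = 2)
  w2 <- apply_elevation_factors(adm2$records, sc$schema,
                                area_ids = adm2$population$area_ids)
  expect_lt(nrow(adm2$records), nrow(adm1$records))
  expect_equal(sum(w2) / sum(w1), 1, tolerance = 0.1)
})

test_that("weighted ASRs converge to the generating standardized rate", {
  sc <- synthetic_scenario(rows = 2, cols = 2, pop_median = 2e6,
                           pop_sdlog = 0, mean_expected = 5000,
                           tau_h = Inf, tau_b = Inf, seed = 17)
  adm <- simulate_admissions(sc, weight_model = "gamma", mean_weight = 10)
  w <- apply_elevation_factors(adm$records, sc$schema,
                               area_ids = adm$population$area_ids)
  std <- pooled_standard(adm$population)
  asr <- direct_standardized_rate(w, adm$population, std)
  # oracle: plug the generating rates straight into the standard weights
  target <- sum(std$weights * adm$rates$rates)
  expect_equal(unname(mean(asr)), target, tolerance = 0.05)
  # design consistency: doubled weights, halved records, same expectation
  adm_w2 <- simulate_admissions(sc, weight_model = "constant",
                                mean_weight = 20)
  w2 <- apply_elevation_factors(adm_w2$records, sc$schema,
                                area_ids = adm_w2$population$area_ids)
  expect_equal(sum(w2) / sum(w), 1, tolerance = 0.1)
})
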