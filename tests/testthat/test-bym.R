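test_that("ICAR pairwise sum matches a brute-force double loop", {
  g2 <- adjacency_graph(c("a", "b"), cbind("a", "b"))
  expect_equal(icar_pairwise_sum(c(1, -1), g2), 4)
  expect_equal(icar_pairwise_sum(c(3, 3), g2), 0)

  set.seed(101)
  for (i in 1:20) {
    g <- random_graph(sample(2:6, 1L))
    h <- rnorm(length(g$area_ids))
    # brute force: loop over all ordered pairs with an adjacency indicator
    n <- length(h)
    adj <- matrix(FALSE, n, n)
    adj[g$edges] <- TRUE
    brute <- 0
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a < b && (adj[a, b] || adj[b, a])) brute <- brute + (h[a] - h[b])^2
    }
    expect_equal(icar_pairwise_sum(h, g), brute, tolerance = 1e-13)
  }
})

test_that("ICAR log-density follows the rank-deficient closed form", {
  g2 <- adjacency_graph(c("a", "b"), cbind("a", "b"))
  expect_equal(icar_logdensity(c(1, -1), 2, g2), 0.5 * log(2) - 4)
  expect_equal(icar_logdensity(c(0, 0), 3, g2), 0.5 * log(3))
  set.seed(5)
  g <- random_graph(6L)
  h <- rnorm(6); h <- h - ave(h, g$components)
  expect_equal(icar_logdensity(h, 1, g), -icar_pairwise_sum(h, g) / 2)
  expect_error(icar_logdensity(h, 0, g), "positive")
})

test_that("the Poisson log-likelihood matches summed dpois up to the constant", {
  set.seed(9)
  n <- 8L
  o <- rpois(n, 6); e <- runif(n, 0.5, 4)
  alpha <- 0.3; h <- rnorm(n, sd = 0.2); b <- rnorm(n, sd = 0.2)
  lam <- e * exp(alpha + h + b)
  oracle <- sum(dpois(o, lam, log = TRUE)) + sum(lfactorial(o))
  expect_equal(bym_loglikelihood(o, e, alpha, h, b), oracle,
               tolerance = 1e-12)
  # O = E at unit risk: sum O log E - E
  expect_equal(bym_loglikelihood(o, o), sum(o * log(o) - o))
  expect_equal(bym_loglikelihood(0, 2, 0.1), -2 * exp(0.1))
  expect_error(bym_loglikelihood(3, 0), "zero expected")
})

test_that("precision Gibbs draws follow the conjugate Gamma posteriors", {
  g2 <- adjacency_graph(c("a", "b"), cbind("a", "b"))
  set.seed(21)
  draws <- replicate(2e4, gibbs_update_tau_h(c(1, -1), g2, 1, 0.0005))
  # Gamma(1 + 1/2, 0.0005 + 2): mean = shape/rate
  shp <- 1.5; rt <- 2.0005
  se_mean <- sqrt(shp / rt^2) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - shp / rt), 3 * se_mean)

  # n = c (no edges): posterior equals the prior
  g_iso <- adjacency_graph(c("a", "b"))
  set.seed(22)
  d0 <- replicate(2e4, gibbs_update_tau_h(c(0, 0), g_iso, 2, 1))
  expect_lt(abs(mean(d0) - 2), 3 * sqrt(2) / sqrt(length(d0)))

  # heterogeneity: b = (2), shape 1, rate 1 -> Gamma(1.5, 3)
  set.seed(23)
  db <- replicate(2e4, gibbs_update_tau_b(2, 1, 1))
  expect_lt(abs(mean(db) - 0.5), 3 * sqrt(1.5 / 9) / sqrt(length(db)))
  # zero vector: prior Gamma(shape + n/2, rate)
  set.seed(24)
  dz <- replicate(2e4, gibbs_update_tau_b(c(0, 0), 1, 2))
  expect_lt(abs(mean(dz) - 1), 3 * sqrt(2 / 4) / sqrt(length(dz)))
})

test_that("Metropolis sweeps keep the spatial effect centred and risks coherent", {
  set.seed(31)
  g <- make_lattice(4, 4)
  n <- 16L
  o <- rpois(n, 10); e <- rep(10, n)
  state <- list(alpha = 0.2, h = rnorm(n, sd = 0.1), b = rnorm(n, sd = 0.1),
                tau_h = 2, tau_b = 5)
  state$h <- state$h - mean(state$h)
  scales <- list(h = 0.3, b = 0.3, alpha = 0.1)
  for (k in 1:20) {
    state <- mh_update_effects(state, o, e, g, scales)
    expect_lt(abs(sum(state$h)), 1e-10)
  }
  expect_true(state$acc_h > 0 && state$acc_h <= 1)
})

test_that("recentring shifts alpha so fitted risks are unchanged on a connected graph", {
  set.seed(32)
  g <- make_lattice(3, 3)
  n <- 9L
  o <- rpois(n, 8); e <- rep(8, n)
  h0 <- rnorm(n, sd = 0.2)  # deliberately uncentred
  state <- list(alpha = 0.1, h = h0, b = numeric(n), tau_h = 1, tau_b = 1)
  lambda_before <- exp(state$alpha + state$h + state$b)
  # freeze every move: only the recentring acts
  expect_warning(
    out <- mh_update_effects(state, o, e, g,
                             list(h = 0, b = 0, alpha = 0),
                             heterogeneity = FALSE,
                             update_intercept = FALSE),
    "frozen")
  expect_true(out$frozen)
  expect_lt(abs(sum(out$h)), 1e-12)
  lambda_after <- exp(out$alpha + out$h + out$b)
  expect_equal(lambda_after, lambda_before, tolerance = 1e-12)
  # zero-scale sites count as accepted by convention
  expect_equal(out$acc_h, 1)
})

test_that("posterior summaries report means, central intervals and exceedance", {
  draws <- cbind(a1 = c(0.5, 1.5), a2 = c(2, 3))
  ps <- posterior_summaries(draws)
  expect_equal(ps$rr_mean, c(1.0, 2.5))
  expect_equal(ps$pp, c(0.5, 1.0))
  expect_equal(ps$area_id, c("a1", "a2"))
  expect_true(all(ps$rr_q025 <= ps$rr_q975))
  expect_error(posterior_summaries(matrix(numeric(0), 0, 2)), "no draws")

  # PP equals one minus the empirical CDF at the threshold
  set.seed(41)
  x <- matrix(rlnorm(500, sdlog = 0.4), ncol = 1)
  for (thr in c(0.8, 1, 1.3)) {
    expect_equal(posterior_summaries(x, thr)$pp,
                 1 - ecdf(x)(thr))
  }
})

test_that("fit_bym is bit-deterministic given a seed and shrinks raw SMRs", {
  sc <- synthetic_scenario(rows = 6, cols = 6, mean_expected = 10, seed = 4)
  sim <- simulate_registry(sc)
  r <- reference_rates(sim$events, sim$population)
  e <- expected_counts(r, sim$population)
  cfg <- bym_config(n_iterations = 3000, n_burnin = 1000, thinning = 2,
                    seed = 77, ess_warn = 0)
  f1 <- fit_bym(sim$events, e, sim$graph, cfg)
  f2 <- fit_bym(sim$events, e, sim$graph, cfg)
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$draws$rr, f2$draws$rr)

  ok <- !is.na(f1$summary$rr_mean)
  expect_lt(var(f1$summary$rr_mean[ok]), var(f1$summary$smr[ok]))
  expect_true(all(f1$summary$pp[ok] >= 0 & f1$summary$pp[ok] <= 1))
  expect_true(all(f1$summary$rr_q025[ok] <= f1$summary$rr_q975[ok]))
})

test_that("areas without population are dropped and reported as missing", {
  s <- age_schema("all", 0)
  ids <- c("A", "B", "C")
  ev <- event_table(ids, c(5, 0, 3))
  e <- structure(c(A = 5, B = 0, C = 4), class = "expected_counts")
  names(e) <- ids
  g <- adjacency_graph(ids, rbind(c("A", "B"), c("B", "C")))
  cfg <- bym_config(n_iterations = 1500, n_burnin = 500, seed = 9,
                    ess_warn = 0)
  fit <- suppressWarnings(fit_bym(ev, e, g, cfg))
  expect_equal(fit$dropped_areas, "B")
  expect_true(is.na(fit$summary$rr_mean[fit$summary$area_id == "B"]))
  expect_false(anyNA(fit$summary$rr_mean[fit$summary$area_id != "B"]))

  e_bad <- structure(c(A = 5, B = 0, C = 0), class = "expected_counts")
  names(e_bad) <- ids
  expect_error(fit_bym(ev, e_bad, g, cfg), "zero expected")
})
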