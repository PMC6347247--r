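#' Configuration for the BYM sampler
#'
#' Hyperpriors and MCMC settings for [fit_bym()]. Both precisions get
#' Gamma(shape, rate) priors; the default Gamma(1, 0.0005) is weakly
#' informative on the precision scale and is the historical default for
#' log-precision hyperparameters in Bayesian disease-mapping software.
#' The intercept carries a flat prior.
#'
#' @param n_iterations Total MCMC sweeps.
#' @param n_burnin Burn-in sweeps (discarded; proposal scales adapt only
#'   here).
#' @param thinning Keep every `thinning`-th post-burn-in sweep.
#' @param seed Optional integer seed; fixing it makes the fit
#'   deterministic.
#' @param prior_tau_h,prior_tau_b Length-2 numeric `c(shape, rate)` for the
#'   Gamma hyperpriors on the spatial and heterogeneity precisions.
#' @param init_scale Initial random-walk proposal standard deviation.
#' @param spatial,heterogeneity Logical; disable to fix `h` (resp. `b`)
#'   at zero.
#' @param alpha_flat Logical; `TRUE` (default) updates the intercept under
#'   a flat prior, `FALSE` fixes it at zero.
#' @param adapt Logical; Robbins-Monro tuning of proposal scales toward
#'   `target_acceptance` during burn-in (frozen afterwards).
#' @param target_acceptance Target single-site acceptance rate.
#' @param ess_warn Warn when the minimum effective sample size across area
#'   relative risks falls below this.
#' @param keep_draws Retain the relative-risk draw matrix in the fit.
#' @return An object of class `bym_config`.
#' @export
bym_config <- function(n_iterations = 50000L, n_burnin = 10000L,
                       thinning = 10L, seed = NULL,
                       prior_tau_h = c(shape = 1, rate = 0.0005),
                       prior_tau_b = c(shape = 1, rate = 0.0005),
                       init_scale = 0.1, spatial = TRUE, heterogeneity = TRUE,
                       alpha_flat = TRUE, adapt = TRUE,
                       target_acceptance = 0.44, ess_warn = 100,
                       keep_draws = TRUE) {
  stopifnot(length(prior_tau_h) == 2L, length(prior_tau_b) == 2L)
  if (any(c(prior_tau_h, prior_tau_b) <= 0)) {
    stop("hyperprior shapes and rates must be positive", call. = FALSE)
  }
  n_iterations <- as.integer(n_iterations)
  n_burnin <- as.integer(n_burnin)
  thinning <- as.integer(thinning)
  if (n_burnin >= n_iterations) {
    stop("`n_burnin` must be smaller than `n_iterations`", call. = FALSE)
  }
  if (thinning < 1L) stop("`thinning` must be >= 1", call. = FALSE)
  if (init_scale <= 0) stop("`init_scale` must be positive", call. = FALSE)
  structure(list(n_iterations = n_iterations, n_burnin = n_burnin,
                 thinning = thinning, seed = seed,
                 prior_tau_h = unname(prior_tau_h),
                 prior_tau_b = unname(prior_tau_b),
                 init_scale = init_scale, spatial = spatial,
                 heterogeneity = heterogeneity, alpha_flat = alpha_flat,
                 adapt = adapt, target_acceptance = target_acceptance,
                 ess_warn = ess_warn, keep_draws = keep_draws),
            class = "bym_config")
}

#' @export
print.bym_config <- function(x, ...) {
  cat("<bym_config> ", x$n_iterations, " iterations (burn-in ", x$n_burnin,
      ", thin ", x$thinning, "), tau priors Gamma(",
      x$prior_tau_h[1], ", ", x$prior_tau_h[2], ") / Gamma(",
      x$prior_tau_b[1], ", ", x$prior_tau_b[2], ")\n", sep = "")
  invisible(x)
}

#' ICAR pairwise squared-difference sum
#'
#' `S = sum over undirected edges (i,j) of (h_i - h_j)^2`, each edge counted
#' once — the quadratic form of the intrinsic CAR prior.
#'
#' @param h Numeric effect vector aligned to the graph nodes.
#' @param graph An `adjacency_graph`.
#' @return Non-negative scalar.
#' @export
icar_pairwise_sum <- function(h, graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (length(h) != length(graph$area_ids)) {
    stop("`h` must have one entry per graph node", call. = FALSE)
  }
  e <- graph$edges
  if (!nrow(e)) return(0)
  sum((h[e[, 1L]] - h[e[, 2L]])^2)
}

#' ICAR log-density (up to an additive constant)
#'
#' `((n - c)/2) * log(tau) - (tau/2) * S` with `n` nodes and `c` connected
#' components: the intrinsic CAR precision `tau * L` (graph Laplacian) is
#' rank-deficient by one per component, so the normalizing power of `tau`
#' is `(n - c)/2`, defined on the sum-to-zero subspace.
#'
#' @inheritParams icar_pairwise_sum
#' @param tau_h Positive spatial precision.
#' @return Log-density value (additive constant omitted).
#' @export
icar_logdensity <- function(h, tau_h, graph) {
  if (!is.numeric(tau_h) || length(tau_h) != 1L || tau_h <= 0) {
    stop("`tau_h` must be a positive scalar", call. = FALSE)
  }
  s <- icar_pairwise_sum(h, graph)
  n <- length(graph$area_ids)
  ((n - graph$n_components) / 2) * log(tau_h) - (tau_h / 2) * s
}

#' Poisson log-likelihood of the BYM model
#'
#' `sum_i [O_i (log E_i + alpha + h_i + b_i) - E_i exp(alpha + h_i + b_i)]`,
#' the Poisson log-likelihood of `O_i ~ Poisson(E_i * lambda_i)` with the
#' data-independent `-log(O_i!)` term omitted. Areas with `E = 0` and
#' `O = 0` are excluded; `E = 0` with `O > 0` is an error.
#'
#' @param observed,expected Aligned numeric vectors of observed and expected
#'   counts.
#' @param alpha Scalar intercept.
#' @param h,b Effect vectors (defaults zero).
#' @return Scalar log-likelihood up to a constant.
#' @export
bym_loglikelihood <- function(observed, expected, alpha = 0,
                              h = numeric(length(observed)),
                              b = numeric(length(observed))) {
  stopifnot(length(observed) == length(expected),
            length(h) == length(observed), length(b) == length(observed))
  if (any(expected == 0 & observed > 0)) {
    stop("positive observed count with zero expected", call. = FALSE)
  }
  keep <- !(expected == 0 & observed == 0)
  o <- observed[keep]; e <- expected[keep]
  eta <- alpha + h[keep] + b[keep]
  sum(o * (log(e) + eta) - e * exp(eta))
}

#' Gibbs draws for the BYM precisions
#'
#' The Gamma hyperpriors are conjugate to the Gaussian random-effect
#' layers: the spatial precision's full conditional is
#' `Gamma(shape + (n - c)/2, rate + S/2)` with `S` the ICAR pairwise sum,
#' and the heterogeneity precision's is
#' `Gamma(shape + n/2, rate + sum(b^2)/2)`.
#'
#' @param h Spatial effect vector (sum-to-zero per component).
#' @param graph An `adjacency_graph`.
#' @param b Heterogeneity effect vector.
#' @param prior_shape,prior_rate Positive Gamma hyperprior parameters.
#' @return A single precision draw.
#' @export
gibbs_update_tau_h <- function(h, graph, prior_shape, prior_rate) {
  stopifnot(prior_shape > 0, prior_rate > 0)
  s <- icar_pairwise_sum(h, graph)
  n <- length(graph$area_ids)
  stats::rgamma(1L, shape = prior_shape + (n - graph$n_components) / 2,
                rate = prior_rate + s / 2)
}

#' @rdname gibbs_update_tau_h
#' @export
gibbs_update_tau_b <- function(b, prior_shape, prior_rate) {
  stopifnot(prior_shape > 0, prior_rate > 0)
  stats::rgamma(1L, shape = prior_shape + length(b) / 2,
                rate = prior_rate + sum(b^2) / 2)
}

# CSR neighbour encoding for the compiled sampler
graph_csr <- function(graph) {
  nbs <- neighbor_lists(graph)
  deg <- lengths(nbs)
  list(flat = as.integer(unlist(nbs) - 1L),
       start = as.integer(c(0L, cumsum(deg))))
}

#' One Metropolis sweep over the BYM effects
#'
#' Updates every `h_i`, then recentres `h` to sum zero per connected
#' component (the intercept absorbing the shift, so fitted risks are
#' unchanged on a connected graph), then every `b_i`, then the intercept —
#' each by single-site random-walk Metropolis against its full conditional.
#' Exposed mainly for testing and diagnostics; [fit_bym()] runs the same
#' compiled sweep internally.
#'
#' @param state List with elements `alpha`, `h`, `b`, `tau_h`, `tau_b`.
#' @param observed,expected Aligned count vectors (areas in the model).
#' @param graph An `adjacency_graph` over the same areas.
#' @param proposal_scales List with elements `h`, `b` (vectors) and `alpha`
#'   (scalar); a zero scale freezes the chain at that site, counted as
#'   accepted by convention and flagged in the result.
#' @param spatial,heterogeneity,update_intercept Logical switches matching
#'   [bym_config()].
#' @return The updated state plus acceptance rates (`acc_h`, `acc_b`,
#'   `acc_alpha`) and a `frozen` flag.
#' @export
mh_update_effects <- function(state, observed, expected, graph,
                              proposal_scales, spatial = TRUE,
                              heterogeneity = TRUE, update_intercept = TRUE) {
  stopifnot(inherits(graph, "adjacency_graph"))
  n <- length(graph$area_ids)
  stopifnot(length(state$h) == n, length(state$b) == n,
            length(observed) == n, length(expected) == n)
  csr <- graph_csr(graph)
  sc_h <- rep_len(proposal_scales$h, n)
  sc_b <- rep_len(proposal_scales$b, n)
  frozen <- any(sc_h == 0) || any(sc_b == 0) || proposal_scales$alpha == 0
  res <- bym_sweep_cpp(state$alpha, state$h, state$b, state$tau_h,
                       state$tau_b, as.numeric(observed),
                       as.numeric(expected), csr$flat, csr$start,
                       graph$components - 1L, graph$n_components,
                       log(sc_h), log(sc_b), log(proposal_scales$alpha),
                       spatial, heterogeneity, update_intercept)
  state$alpha <- res$alpha
  state$h <- res$h
  state$b <- res$b
  state$acc_h <- res$acc_h
  state$acc_b <- res$acc_b
  state$acc_alpha <- res$acc_alpha
  state$frozen <- frozen
  if (frozen) {
    warning("zero proposal scale: chain frozen at those sites", call. = FALSE)
  }
  state
}

#' Fit the Besag-York-Mollie model by MCMC
#'
#' Hierarchical Poisson model for smoothed small-area relative risks:
#' `O_i ~ Poisson(E_i * lambda_i)`, `log(lambda_i) = alpha + h_i + b_i`,
#' with an intrinsic CAR prior on the spatially structured effect `h`
#' (neighbourhoods from `graph`) and an exchangeable Gaussian prior on the
#' heterogeneity effect `b`. Precisions get Gamma hyperpriors and
#' conjugate Gibbs updates; `alpha`, `h`, `b` move by adaptively tuned
#' single-site random-walk Metropolis. Areas with `E = 0` and `O = 0` are
#' dropped from the likelihood and reported with missing risk.
#'
#' @param events An `event_table` (or named numeric vector of observed
#'   counts).
#' @param expected An `expected_counts` vector aligned to the same areas.
#' @param graph An `adjacency_graph` over the same areas.
#' @param config A [bym_config()].
#' @return A `bym_fit` object: `summary` data.frame (`area_id`, `observed`,
#'   `expected`, `smr`, `rr_mean`, `rr_q025`, `rr_q975`, `pp`), posterior
#'   summaries of `alpha`/`tau_h`/`tau_b`, acceptance rates, effective
#'   sample sizes and (optionally) the relative-risk draw matrix.
#' @export
fit_bym <- function(events, expected, graph, config = bym_config()) {
  stopifnot(inherits(graph, "adjacency_graph"),
            inherits(config, "bym_config"))
  o_all <- if (inherits(events, "event_table")) event_totals(events) else events
  ids <- names(o_all)
  if (is.null(ids)) stop("observed counts must be named by area", call. = FALSE)
  e_all <- as.numeric(expected)[match(ids, names(expected))]
  if (anyNA(e_all)) {
    stop("expected counts missing for some areas", call. = FALSE)
  }
  if (!setequal(ids, graph$area_ids)) {
    stop("graph nodes do not match event-table areas", call. = FALSE)
  }
  if (any(e_all == 0 & o_all > 0)) {
    stop("positive observed count with zero expected in area(s): ",
         paste(ids[e_all == 0 & o_all > 0], collapse = ", "), call. = FALSE)
  }
  keep <- e_all > 0
  if (!any(keep)) stop("no areas with positive expected counts", call. = FALSE)
  kept_ids <- ids[keep]
  sub <- induced_subgraph_ids(graph, kept_ids)
  csr <- graph_csr(sub)
  o <- as.numeric(o_all[kept_ids])
  e <- e_all[keep]

  if (!is.null(config$seed)) set.seed(config$seed)
  raw <- bym_mcmc_cpp(o, e, csr$flat, csr$start, sub$components - 1L,
                      sub$n_components, config$n_iterations,
                      config$n_burnin, config$thinning,
                      config$prior_tau_h[1], config$prior_tau_h[2],
                      config$prior_tau_b[1], config$prior_tau_b[2],
                      config$init_scale, config$spatial,
                      config$heterogeneity, config$alpha_flat,
                      config$adapt, config$target_acceptance)
  colnames(raw$rr) <- kept_ids
  ps <- posterior_summaries(raw$rr, threshold = 1)

  summary_df <- data.frame(
    area_id = ids, observed = unname(o_all), expected = e_all,
    smr = ifelse(e_all > 0, o_all / e_all, NA_real_),
    rr_mean = NA_real_, rr_q025 = NA_real_, rr_q975 = NA_real_,
    pp = NA_real_, stringsAsFactors = FALSE)
  m <- match(kept_ids, ids)
  summary_df$rr_mean[m] <- ps$rr_mean
  summary_df$rr_q025[m] <- ps$rr_q025
  summary_df$rr_q975[m] <- ps$rr_q975
  summary_df$pp[m] <- ps$pp

  ess <- apply(raw$rr, 2L, ess_univariate)
  if (min(ess) < config$ess_warn) {
    warning(sprintf(
      "minimum effective sample size %.0f below %g; consider a longer run",
      min(ess), config$ess_warn), call. = FALSE)
  }
  fit <- list(
    summary = summary_df,
    alpha = summarize_scalar(raw$alpha),
    tau_h = if (config$spatial) summarize_scalar(raw$tau_h) else NULL,
    tau_b = if (config$heterogeneity) summarize_scalar(raw$tau_b) else NULL,
    acceptance = c(h = raw$acc_h, b = raw$acc_b, alpha = raw$acc_alpha),
    ess = ess,
    n_kept = nrow(raw$rr),
    dropped_areas = ids[!keep],
    config = config,
    draws = if (config$keep_draws) {
      list(rr = raw$rr, alpha = raw$alpha, tau_h = raw$tau_h,
           tau_b = raw$tau_b)
    })
  class(fit) <- "bym_fit"
  fit
}

induced_subgraph_ids <- function(graph, ids) {
  if (length(ids) == length(graph$area_ids)) return(graph)
  keep_idx <- match(ids, graph$area_ids)
  e <- graph$edges
  sel <- e[, 1L] %in% keep_idx & e[, 2L] %in% keep_idx
  e <- e[sel, , drop = FALSE]
  adjacency_graph(ids, cbind(graph$area_ids[e[, 1L]],
                             graph$area_ids[e[, 2L]]))
}

summarize_scalar <- function(x) {
  c(mean = mean(x), sd = stats::sd(x),
    q025 = unname(stats::quantile(x, 0.025)),
    q975 = unname(stats::quantile(x, 0.975)))
}

# initial-positive-sequence estimator of the effective sample size
ess_univariate <- function(x) {
  n <- length(x)
  if (n < 10L || stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE,
                    demean = TRUE)$acf[-1L]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}

#' Summarize relative-risk draws
#'
#' Per-area posterior mean, central 95% interval and exceedance probability
#' `PP = Pr(RR > threshold)` (the fraction of kept draws above the
#' threshold, i.e. one minus the empirical CDF at the threshold).
#'
#' @param draws Matrix of kept draws, iterations x areas.
#' @param threshold Exceedance threshold on the relative-risk scale.
#' @return Data.frame with columns `area_id` (when draws are named),
#'   `rr_mean`, `rr_q025`, `rr_q975`, `pp`.
#' @export
posterior_summaries <- function(draws, threshold = 1.0) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 1L) stop("no draws to summarize", call. = FALSE)
  q <- apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975),
             names = FALSE)
  out <- data.frame(
    rr_mean = colMeans(draws),
    rr_q025 = q[1L, ],
    rr_q975 = q[2L, ],
    pp = colMeans(draws > threshold))
  if (!is.null(colnames(draws))) {
    out <- cbind(data.frame(area_id = colnames(draws),
                            stringsAsFactors = FALSE), out)
  }
  rownames(out) <- NULL
  out
}

#' @export
print.bym_fit <- function(x, ...) {
  s <- x$summary
  ok <- !is.na(s$rr_mean)
  cat("<bym_fit> ", nrow(s), " areas (", sum(!ok), " dropped), ",
      x$n_kept, " kept draws\n", sep = "")
  cat(sprintf("  alpha: %.3f (%.3f, %.3f)\n", x$alpha["mean"],
              x$alpha["q025"], x$alpha["q975"]))
  if (!is.null(x$tau_h))
    cat(sprintf("  tau_h: %.2f (%.2f, %.2f)\n", x$tau_h["mean"],
                x$tau_h["q025"], x$tau_h["q975"]))
  if (!is.null(x$tau_b))
    cat(sprintf("  tau_b: %.2f (%.2f, %.2f)\n", x$tau_b["mean"],
                x$tau_b["q025"], x$tau_b["q975"]))
  cat(sprintf("  RR range (posterior means): %.3f - %.3f\n",
              min(s$rr_mean[ok]), max(s$rr_mean[ok])))
  cat(sprintf("  acceptance: %s\n",
              paste(names(x$acceptance),
                    sprintf("%.2f", x$acceptance), collapse = ", ")))
  invisible(x)
}
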