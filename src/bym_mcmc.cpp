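#include <Rcpp.h>
using namespace Rcpp;

// Single-site random-walk Metropolis machinery for the BYM model
//   O_i ~ Poisson(E_i * exp(alpha + h_i + b_i))
// with an intrinsic CAR prior on h (pairwise-difference form, each
// undirected edge once) and iid N(0, 1/tau_b) on b. Neighbourhoods are
// passed in CSR form: nb_flat holds 0-based neighbour indices, node i's
// neighbours are nb_flat[nb_start[i] .. nb_start[i+1]-1].

static double sweep_h(NumericVector& h, const NumericVector& b, double alpha,
                      double tau_h, const NumericVector& O,
                      const NumericVector& E, const IntegerVector& nb_flat,
                      const IntegerVector& nb_start, NumericVector& ls,
                      bool adapt, double target, double step) {
  int n = h.size();
  int acc = 0;
  for (int i = 0; i < n; ++i) {
    double scale = std::exp(ls[i]);
    bool accepted;
    if (scale <= 0.0) {
      accepted = true;  // degenerate proposal: counted accepted by convention
    } else {
      double hp = h[i] + scale * norm_rand();
      int deg = nb_start[i + 1] - nb_start[i];
      double nb_sum = 0.0;
      for (int k = nb_start[i]; k < nb_start[i + 1]; ++k)
        nb_sum += h[nb_flat[k]];
      double dprior = -0.5 * tau_h *
        (deg * (hp * hp - h[i] * h[i]) - 2.0 * (hp - h[i]) * nb_sum);
      double lam_base = E[i] * std::exp(alpha + b[i]);
      double dlik = O[i] * (hp - h[i]) -
        lam_base * (std::exp(hp) - std::exp(h[i]));
      accepted = std::log(unif_rand()) < dprior + dlik;
      if (accepted) h[i] = hp;
    }
    if (accepted) ++acc;
    if (adapt) ls[i] += step * ((accepted ? 1.0 : 0.0) - target);
  }
  return (double)acc / n;
}

static double sweep_b(const NumericVector& h, NumericVector& b, double alpha,
                      double tau_b, const NumericVector& O,
                      const NumericVector& E, NumericVector& ls, bool adapt,
                      double target, double step) {
  int n = b.size();
  int acc = 0;
  for (int i = 0; i < n; ++i) {
    double scale = std::exp(ls[i]);
    bool accepted;
    if (scale <= 0.0) {
      accepted = true;
    } else {
      double bp = b[i] + scale * norm_rand();
      double dprior = -0.5 * tau_b * (bp * bp - b[i] * b[i]);
      double lam_base = E[i] * std::exp(alpha + h[i]);
      double dlik = O[i] * (bp - b[i]) -
        lam_base * (std::exp(bp) - std::exp(b[i]));
      accepted = std::log(unif_rand()) < dprior + dlik;
      if (accepted) b[i] = bp;
    }
    if (accepted) ++acc;
    if (adapt) ls[i] += step * ((accepted ? 1.0 : 0.0) - target);
  }
  return (double)acc / n;
}

static double update_alpha(double alpha, const NumericVector& h,
                           const NumericVector& b, const NumericVector& O,
                           const NumericVector& E, double O_tot,
                           double& ls, bool adapt, double target, double step,
                           int& accepted_out) {
  double scale = std::exp(ls);
  bool accepted;
  double out = alpha;
  if (scale <= 0.0) {
    accepted = true;
  } else {
    double ap = alpha + scale * norm_rand();
    double s = 0.0;
    for (int i = 0; i < E.size(); ++i)
      s += E[i] * std::exp(h[i] + b[i]);
    double dlik = O_tot * (ap - alpha) -
      s * (std::exp(ap) - std::exp(alpha));
    accepted = std::log(unif_rand()) < dlik;  // flat prior on alpha
    if (accepted) out = ap;
  }
  if (accepted) accepted_out = 1; else accepted_out = 0;
  if (adapt) ls += step * ((accepted ? 1.0 : 0.0) - target);
  return out;
}

// recentre h to sum zero per component; alpha absorbs the node-weighted
// mean shift (exactly lambda-preserving when there is one component)
static void recentre(NumericVector& h, double& alpha,
                     const IntegerVector& comp, int n_comp) {
  int n = h.size();
  std::vector<double> m(n_comp, 0.0);
  std::vector<int> cnt(n_comp, 0);
  for (int i = 0; i < n; ++i) { m[comp[i]] += h[i]; ++cnt[comp[i]]; }
  double shift = 0.0;
  for (int k = 0; k < n_comp; ++k) {
    m[k] /= cnt[k];
    shift += m[k] * cnt[k];
  }
  for (int i = 0; i < n; ++i) h[i] -= m[comp[i]];
  alpha += shift / n;
}

static double pairwise_sum(const NumericVector& h,
                           const IntegerVector& nb_flat,
                           const IntegerVector& nb_start) {
  double s = 0.0;
  for (int i = 0; i < h.size(); ++i)
    for (int k = nb_start[i]; k < nb_start[i + 1]; ++k) {
      int j = nb_flat[k];
      if (j > i) { double d = h[i] - h[j]; s += d * d; }
    }
  return s;
}

// one full Metropolis sweep (h sites, recentre, b sites, alpha) — the unit
// the R-level mh_update_effects() exposes for testing
// [[Rcpp::export]]
List bym_sweep_cpp(double alpha, NumericVector h, NumericVector b,
                   double tau_h, double tau_b, NumericVector O,
                   NumericVector E, IntegerVector nb_flat,
                   IntegerVector nb_start, IntegerVector comp, int n_comp,
                   NumericVector ls_h, NumericVector ls_b, double ls_alpha,
                   bool spatial, bool heterogeneity, bool update_intercept) {
  NumericVector h2 = clone(h), b2 = clone(b);
  NumericVector lsh = clone(ls_h), lsb = clone(ls_b);
  double O_tot = sum(O);
  double acc_h = NA_REAL, acc_b = NA_REAL;
  int acc_a = NA_INTEGER;
  if (spatial) {
    acc_h = sweep_h(h2, b2, alpha, tau_h, O, E, nb_flat, nb_start,
                    lsh, false, 0.44, 0.0);
    recentre(h2, alpha, comp, n_comp);
  }
  if (heterogeneity)
    acc_b = sweep_b(h2, b2, alpha, tau_b, O, E, lsb, false, 0.44, 0.0);
  if (update_intercept) {
    double lsa = ls_alpha;
    alpha = update_alpha(alpha, h2, b2, O, E, O_tot, lsa, false, 0.44,
                         0.0, acc_a);
  }
  return List::create(_["alpha"] = alpha, _["h"] = h2, _["b"] = b2,
                      _["acc_h"] = acc_h, _["acc_b"] = acc_b,
                      _["acc_alpha"] = acc_a);
}

// [[Rcpp::export]]
List bym_mcmc_cpp(NumericVector O, NumericVector E, IntegerVector nb_flat,
                  IntegerVector nb_start, IntegerVector comp, int n_comp,
                  int n_iter, int n_burn, int thin, double shape_h,
                  double rate_h, double shape_b, double rate_b,
                  double init_scale, bool spatial, bool heterogeneity,
                  bool update_intercept, bool adapt, double target) {
  int n = O.size();
  NumericVector h(n, 0.0), b(n, 0.0);
  double alpha = 0.0, tau_h = 10.0, tau_b = 10.0;
  double ls0 = std::log(init_scale);
  NumericVector ls_h(n, ls0), ls_b(n, ls0);
  double ls_a = ls0;
  double O_tot = sum(O);
  int rank_icar = n - n_comp;

  int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix rr_draws(n_keep, n);
  NumericVector alpha_draws(n_keep), tauh_draws(n_keep), taub_draws(n_keep);
  double acc_h_sum = 0.0, acc_b_sum = 0.0, acc_a_sum = 0.0;
  int post_sweeps = 0, kept = 0;

  for (int t = 0; t < n_iter; ++t) {
    bool burn = t < n_burn;
    double step = burn && adapt ?
      std::min(0.25, 2.0 / std::sqrt((double)(t + 1))) : 0.0;
    bool do_adapt = burn && adapt;
    if (spatial) {
      double a = sweep_h(h, b, alpha, tau_h, O, E, nb_flat, nb_start,
                         ls_h, do_adapt, target, step);
      recentre(h, alpha, comp, n_comp);
      double S = pairwise_sum(h, nb_flat, nb_start);
      tau_h = R::rgamma(shape_h + 0.5 * rank_icar, 1.0 / (rate_h + 0.5 * S));
      if (!burn) acc_h_sum += a;
    }
    if (heterogeneity) {
      double a = sweep_b(h, b, alpha, tau_b, O, E, ls_b, do_adapt,
                         target, step);
      double ssb = 0.0;
      for (int i = 0; i < n; ++i) ssb += b[i] * b[i];
      tau_b = R::rgamma(shape_b + 0.5 * n, 1.0 / (rate_b + 0.5 * ssb));
      if (!burn) acc_b_sum += a;
    }
    if (update_intercept) {
      int acc_a;
      alpha = update_alpha(alpha, h, b, O, E, O_tot, ls_a, do_adapt,
                           target, step, acc_a);
      if (!burn) acc_a_sum += acc_a;
    }
    if (!burn) {
      ++post_sweeps;
      if ((t - n_burn) % thin == thin - 1 && kept < n_keep) {
        for (int i = 0; i < n; ++i)
          rr_draws(kept, i) = std::exp(alpha + h[i] + b[i]);
        alpha_draws[kept] = alpha;
        tauh_draws[kept] = tau_h;
        taub_draws[kept] = tau_b;
        ++kept;
      }
    }
  }
  return List::create(
    _["rr"] = rr_draws, _["alpha"] = alpha_draws,
    _["tau_h"] = tauh_draws, _["tau_b"] = taub_draws,
    _["acc_h"] = spatial && post_sweeps ? acc_h_sum / post_sweeps : NA_REAL,
    _["acc_b"] = heterogeneity && post_sweeps ?
                   acc_b_sum / post_sweeps : NA_REAL,
    _["acc_alpha"] = update_intercept && post_sweeps ?
                   acc_a_sum / post_sweeps : NA_REAL,
    _["final_scales_h"] = exp(ls_h), _["final_scales_b"] = exp(ls_b),
    _["final_scale_alpha"] = std::exp(ls_a));
}
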