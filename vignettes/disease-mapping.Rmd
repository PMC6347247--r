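---
title: "Methods: age standardization and BYM smoothing of small-area risks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age standardization and BYM smoothing of small-area risks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bymsmooth)
```

## Scope and data model

`bymsmooth` analyses registry-style inputs: an event table (deaths or
hospital admissions) by area and age group, a mid-period population table
by area and age group with a period multiplier, and an area contiguity
graph. Area identifiers are opaque strings joined by exact match. The
default age schema has 18 five-year groups (0–4, …, 85+), the
stratification national statistical institutes use for municipal rolls;
since registry groupings vary, every reader takes an explicit
`age_schema` and the default is an assumption, not a fact about any
particular registry. Areas present in the population roll but absent from
the event file get an observed count of zero — in registry semantics the
absence of a death record *is* a zero, not missing data.

## Standardization

Indirect standardization computes expected counts by applying reference
age-specific rates to each area's person-years,
$E_i = \sum_g r_g \, n_{ig} \, T$, with $T$ the period length in years
(the "mid-period population × period" convention). When the reference
rates are computed from the pooled study data itself,
$\sum_i E_i = \sum_i O_i$ holds as an algebraic identity; the test suite
asserts it to $10^{-9}$ relative tolerance. SMRs are $O_i / E_i$; a $0/0$
is flagged undefined and propagated (the spatial model drops such areas
from the likelihood and reports a missing risk), while $O_i > 0$ with
$E_i = 0$ is rejected as corrupt input.

For survey-based morbidity data the package first expands sampled
discharge records by their elevation factors (weighted counts are sums of
weights), then age-adjusts. Whether a given analysis of admission rates
used direct or indirect standardization is often left unstated in
published work; both are implemented here, and **direct** standardization
with the pooled national age distribution of the same period as the
standard is the default, because ratios of directly standardized rates
against the national rate are exactly 1 for the pooled data itself — the
natural reading of "national rates as the reference". The SIR-style
indirect route is available via `indirect_standardized_ratio()`.

## The BYM model and its sampler

The smoothing model is the Besag–York–Mollié hierarchical Poisson model

$$O_i \sim \mathrm{Poisson}(E_i \lambda_i), \qquad
  \log \lambda_i = \alpha + h_i + b_i,$$

with an intrinsic CAR (ICAR) prior on the spatial effect $h$ and an
exchangeable $N(0, 1/\tau_b)$ prior on the heterogeneity effect $b$. The
ICAR prior is the improper Gaussian Markov random field

$$p(h \mid \tau_h) \propto \tau_h^{(n-c)/2}
  \exp\Big(-\frac{\tau_h}{2} \sum_{i \sim j} (h_i - h_j)^2\Big),$$

with each undirected edge counted once. Its precision matrix is
$\tau_h L$ with $L$ the graph Laplacian, rank-deficient by one per
connected component — hence the exponent $(n-c)/2$ and one sum-to-zero
constraint per component. Under this parameterization the constrained law
of the difference on a two-node path is $N(0, 1/\tau_h)$; the generator's
tests check exactly that closed form via the single positive Laplacian
eigenvalue.

Inference is by MCMC. Deterministic approximations (nested Laplace
schemes) fit this model class faster at scale, but an MCMC implementation
is self-contained, exact in the limit, and lets every conditional be
verified against closed forms; the contract is on the posterior, not the
algorithm. The sweep structure is:

* **Precisions** — conjugate Gibbs:
  $\tau_h \mid h \sim \Gamma(a_h + (n-c)/2,\; r_h + S/2)$ with $S$ the
  pairwise sum, and $\tau_b \mid b \sim \Gamma(a_b + n/2,\; r_b + \sum
  b_i^2/2)$. Default hyperpriors are $\Gamma(1, 0.0005)$ on both — the
  long-standing default for log-precision hyperparameters in disease-
  mapping software, weakly informative across the precision magnitudes
  that arise here; both are configurable in `bym_config()`.
* **Effects** — single-site random-walk Metropolis over all $h_i$, then
  all $b_i$, then $\alpha$ (flat prior), each against its full
  conditional, which touches only the site and its neighbours.
* **Recentring** — after each $h$ sweep, every connected component of $h$
  is recentred to sum zero and $\alpha$ absorbs the node-weighted mean
  shift. On a connected graph this leaves every $\lambda_i$ bit-identical
  (the package asserts it); with several components the per-component
  means differ from their weighted mean by an $O(1/\sqrt{\tau_h n_k})$
  amount and the recentring is the standard centring-on-the-fly for
  constrained ICAR fields. Isolated areas sit in singleton components, so
  their $h_i$ is pinned at zero and their risk is carried entirely by
  $b_i$.
* **Adaptation** — proposal scales follow a Robbins–Monro recursion
  toward 0.44 acceptance (the optimal single-site rate) with step size
  $\min(0.25,\, 2/\sqrt{t})$, active only during burn-in and frozen
  afterwards so the stationary distribution is untouched. A zero proposal
  scale freezes a site; by convention the null move counts as accepted
  and the state is flagged.

Defaults are 50,000 iterations, 10,000 burn-in, thinning 10. Given a seed
the fit is bitwise reproducible. Non-convergence is never an error;
instead the fit warns when the minimum effective sample size across area
risks (initial-positive-sequence estimator) falls below a configurable
threshold. Relative risks are summarized per area by posterior mean,
central 95% interval and the exceedance probability
$PP_i = \Pr(\lambda_i > 1 \mid O)$, computed as one minus the empirical
CDF of the kept draws at 1. Quantile ordering is asserted;
mean-inside-interval is not, since heavy-tailed draws can legitimately
violate it.

Because expected counts are internally standardized, the likelihood
identifies risk only relative to the expected-count-weighted mean of the
generating field; $\alpha$ concentrates near the log of that mean's
inverse. Recovery checks therefore compare the fit to the truth divided
by $\sum_i E^0_i RR_i / \sum_i E^0_i$.

## The synthetic registry generator

The generator exists so that every stage is testable without registry
microdata, which is rarely deposited. It emulates the statistical
structure the analysis assumes:

* **Geography** — a rook-contiguity lattice (default 20×20) standing in
  for municipal contiguity; any explicit graph can be substituted.
* **Population sizes** — log-normal across areas (default median 2,000,
  `sdlog` 1.5, spanning roughly $10^1$–$10^5$ inhabitants), the standard
  stand-in for national municipal size distributions that range from
  hamlets to cities; each area shares a fixed national age pyramid.
* **Age-rate curve** — exponential in the age-group index,
  $r_g \propto e^{0.806 g}$. The slope is calibrated once so that about
  6% of generated deaths fall below the age-65 boundary under the default
  pyramid — the composition typical of prostate-cancer mortality, where
  deaths concentrate in old age — and puts the open-ended 85+ group near
  $4 \times 10^{-3}$ events per person-year, a realistic magnitude. The
  curve is scaled so the mean expected count per area hits
  `mean_expected` (default 4, the sparse regime of cause-specific
  mortality at municipal resolution; recovery studies use 30).
* **Risk field** — $\log RR = h + b$ with $h$ drawn exactly from the
  ICAR law by eigendecomposition of the Laplacian (positive-eigenvalue
  directions only, variance $1/(\tau_h \ell_k)$), plus optional
  multiplicative hot-spot blocks. Events are
  $O_{ig} \sim \mathrm{Poisson}(n_{ig} T r_g RR_i)$.
* **Admissions** — record-level discharges whose counts are Poisson with
  mean $\mu/\bar w$ so that expansion weights of mean $\bar w$ (constant
  or Gamma-distributed) reproduce the target totals in expectation.

What the generator does **not** emulate: real boundary geometry and the
very irregular degree distribution of actual municipal contiguity;
age-by-area interactions (the latent risk is age-constant within an
area); migration, period effects and coding variability between regions.
Passing tests therefore demonstrate correctness of the estimators under
the model's own assumptions, not robustness to their violation.

## Problem sizes and numerical choices in the test suite

The validation studies run on a 20×20 lattice (400 areas) with
$\tau_h = 1$, $\tau_b = 10$ and mean expected count 30 per area, using
22,000 iterations (6,000 burn-in, thinning 8); oracle checks use $10^5$
Gibbs draws and 20,000 kept draws for the degenerate conjugate model.
These sizes give Monte-Carlo errors comfortably below the assertion
tolerances (3–4 standard errors for moment checks) while keeping the full
suite under a minute of sampling time. Under those conditions the fit
recovers a known field with correlation above 0.9 and 95%-interval
coverage near nominal, a signal-free registry yields almost no areas with
$PP > 0.8$, and a planted 2× block is flagged with median $PP$ of 1.

The sparse under-65 stratum of the same field reproduces the well-known
oversmoothing phenomenon: with most areas contributing 0–2 events, the
posterior-mean risk range is strictly narrower than the all-ages range on
the identical latent field. This is demonstrated as a property, not a
number — the degree of compression depends on the realized field.

## Classification and map output

Map legends bin the posterior summaries. Published legends rarely state
their edges, so the defaults are explicitly arbitrary and overridable:
data-driven septiles for the posterior-mean RR and deciles 0.1–0.9 for
PP, with half-open `[a, b)` intervals and outer bins catching the tails.
There is no paper-anchored default for the PP cut-off that colours
"excess risk" areas; it is a user decision. GeoJSON output joins per-area
properties onto supplied geometries, or falls back to lattice points for
synthetic data — adequate for inspection, not cartography.

## Known limitations

* The sampler is single-chain; between-chain diagnostics (R-hat) are out
  of scope, and the effective-sample-size warning is the only automatic
  convergence signal.
* Covariate (ecological regression) terms, proper-CAR/Leroux priors and
  spatio-temporal extensions are not implemented.
* Raw-SMR confidence intervals are not provided: the package's position
  is that mapped inference should come from the smoothed posterior.
* Survey design-effect variance for elevation factors is ignored;
  weighted counts enter the rates as fixed totals.
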