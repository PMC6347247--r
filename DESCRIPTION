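Package: bymsmooth
Title: Small-Area Disease Mapping with Besag-York-Mollie Smoothing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for small-area analysis of mortality and hospital-morbidity
    registries: indirect age standardization (expected counts and standardized
    mortality ratios), direct age standardization with survey expansion weights
    (age-adjusted rates and rate ratios), and Bayesian spatial smoothing of
    area-level relative risks with the Besag-York-Mollie hierarchical Poisson
    model fitted by Markov chain Monte Carlo. Produces per-area posterior mean
    relative risks, credible intervals and exceedance probabilities Pr(RR > 1),
    plus a synthetic registry generator for validation and map-ready GeoJSON
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
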