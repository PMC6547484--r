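# Shared fixtures: all synthetic, built in code at test time.

# small survey configuration for fast end-to-end runs
small_config <- function(seed = 1L, ...) {
  population_config(n_clusters = 60, seed = seed, ...)
}

# single-stratum equal-weight configuration: outcomes depend on wealth rank
# only, so conventional (independence-based) standard errors are valid
homogeneous_config <- function(seed = 1L, n_clusters = 40, ...) {
  population_config(n_clusters = n_clusters, urban_fraction = 0,
                    covariate_effects = FALSE, urban_wealth_shift = 0,
                    seed = seed, ...)
}

# random weighted dataset for estimator-identity property tests
random_ranked <- function(n, rng) {
  h <- stats::rgamma(n, shape = 2, rate = 0.5)
  wealth <- stats::rnorm(n)
  w <- stats::runif(n, 0.2, 3)
  ranked_outcome(h, wealth = wealth, weights = w)
}

# unadjusted regression-route concentration estimate of the ANC count
anc_estimate <- function(pop) {
  ci_regression(ranked_outcome(pop$anc_visits, wealth = pop$wealth_score,
                               weights = pop$sampling_weight))
}
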