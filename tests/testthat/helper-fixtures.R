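# Shared fixtures: small, fast configurations used across test files.

# tiny world: quick enough for repeated MCMC runs
tiny_config <- function(seed = 1, ...) {
  sim_config(n_states = 4L, districts_per_state = 3L,
             clusters_per_district = 4L, individuals_per_cluster = 15L,
             seed = seed, ...)
}

# two-level toy (state and district collapsed): clusters within one area
twolevel_config <- function(seed = 1, n_clusters = 20L, n_ind = 20L,
                            beta0 = -0.3, sigma2_u = 0.3) {
  sim_config(n_states = 1L, districts_per_state = 1L,
             clusters_per_district = n_clusters,
             individuals_per_cluster = n_ind,
             beta0 = beta0, sigma2_f = 0, sigma2_v = 0, sigma2_u = sigma2_u,
             seed = seed)
}

fast_mcmc <- function(seed = 1, ...) {
  mcmc_config(burn_in = 300L, chain_length = 1500L, seed = seed, ...)
}

suppress_degenerate <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("degenerate level", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# population-averaged outcome probability E[invlogit(x)], x ~ N(mu, s2),
# by adaptive numerical integration: the independent oracle for the
# marginal prevalence implied by the generative model
marginal_prevalence <- function(mu, s2) {
  if (s2 == 0) return(invlogit(mu))
  stats::integrate(function(x) invlogit(x) * stats::dnorm(x, mu, sqrt(s2)),
                   lower = mu - 10 * sqrt(s2), upper = mu + 10 * sqrt(s2),
                   rel.tol = 1e-10)$value
}

# E[invlogit(x)^2], x ~ N(mu, s2): used for the between-cluster variance of
# true probabilities in design-effect-aware Monte Carlo standard errors
marginal_prevalence_sq <- function(mu, s2) {
  if (s2 == 0) return(invlogit(mu)^2)
  stats::integrate(function(x) invlogit(x)^2 * stats::dnorm(x, mu, sqrt(s2)),
                   lower = mu - 10 * sqrt(s2), upper = mu + 10 * sqrt(s2),
                   rel.tol = 1e-10)$value
}

# independent percentile oracle: explicit type-7 interpolation from sorted
# order statistics, written without quantile()
manual_percentile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# containment oracle for axis-aligned rectangles (all synthetic polygons)
rect_contains <- function(poly_coords, x, y) {
  x >= min(poly_coords[, 1]) && x <= max(poly_coords[, 1]) &&
    y >= min(poly_coords[, 2]) && y <= max(poly_coords[, 2])
}
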