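# Shared fixtures for the suite. The default synthetic dataset is generated
# once per test run and memoised; tests must not mutate it in place.

options(ehtmarkers.log_level = "warn")

.fixture_env <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (is.null(.fixture_env$ds))
    .fixture_env$ds <- generate_dataset(simulation_config(seed = 101L))
  .fixture_env$ds
}

# Small dense cells x genes matrix with hand-set classes.
tiny_matrix <- function() {
  vals <- matrix(c(500000, 300000, 100000, 100000,
                   250000, 250000, 400000, 100000),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("c1", "c2"),
                                 c("Cd44", "gene_1", "mt-Co1", "ERCC-00001")))
  annotate_gene_classes(expression_matrix(vals))
}

# Brute-force numeric oracle for the Gaussian LRT: minimise each model's RSS
# by 1-D numeric optimisation (variance profiles out analytically), never via
# the closed-form means used by the implementation.
lrt_numeric_oracle <- function(values, labels) {
  g <- as.logical(labels)
  n <- length(values)
  rng <- range(values) + c(-1, 1)
  rss <- function(v, mu) sum((v - mu)^2)
  rss_null <- stats::optimize(function(m) rss(values, m), rng, tol = 1e-12)$objective
  rss_alt <- stats::optimize(function(m) rss(values[g], m), rng, tol = 1e-12)$objective +
    stats::optimize(function(m) rss(values[!g], m), rng, tol = 1e-12)$objective
  n * log(rss_null / rss_alt)
}

# Exact hypergeometric upper-tail by direct enumeration of the pmf via
# binomial coefficients (independent of stats::phyper).
hyper_upper_enum <- function(x, K, N, n) {
  lo <- max(0L, n + K - N)
  hi <- min(n, K)
  xs <- lo:hi
  pmf <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(pmf[xs >= x])
}
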