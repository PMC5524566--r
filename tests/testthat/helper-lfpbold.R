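# Small configurations used across unit tests: a reduced population keeps
# generator/integrator properties testable in seconds.  Acceptance tests use
# the full 200-neuron population (helper-acceptance.R).
small_cfg <- function(n = 40, seed = 1) trial_config(n_neurons = n, rng_seed = seed)
small_pcfg <- function(n = 40, seed = 1) population_config(trial = small_cfg(n, seed))

# Equicorrelated Gaussian sample built independently of the package's
# generator (plain factor construction), for Monte-Carlo cross-checks.
ref_equicorr <- function(n, T, m, sigma, rho) {
  z <- matrix(rnorm(n * T), n, T)
  common <- matrix(rnorm(T), n, T, byrow = TRUE)
  m + sigma * (sqrt(rho) * common + sqrt(1 - rho) * z)
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
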