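# Shared fixtures for the test suite.

# The parameter set estimated for the seven-group adaptation experiment,
# with the psychophysically measured eccentricity law.
fitted_params <- function() pea_params(A = 0.974, B = 0.208,
                                       sigma_p = 11.119, sigma_u = 5.048,
                                       a = 1.853, b = 0.309)

# Noise-free multi-group cycle-mean trajectories from a truth parameter
# set, in the tidy layout the fitting functions consume.
noise_free_groups <- function(params = fitted_params(),
                              thetas = c(2, 4, 8, 16, 32, 64, 95)) {
  do.call(rbind, lapply(thetas, function(theta) {
    tr <- simulate_pea(params, clamp_schedule(theta))
    data.frame(clamp_deg = theta, cycle = tr$cycle, phase = tr$phase,
               mode = tr$mode, hand_deg = tr$extent_deg)
  }))
}

# Random-but-valid PEA parameter draw for property-style tests.
random_pea_params <- function() {
  pea_params(A = stats::runif(1, 0.85, 0.999),
             B = stats::runif(1, 0.05, 0.5),
             sigma_p = stats::runif(1, 4, 25),
             sigma_u = stats::runif(1, 2, 15),
             a = stats::runif(1, 0.8, 5),
             b = stats::runif(1, 0.05, 0.6))
}

# Deterministic logistic observer closure for staircase tests.
logistic_observer <- function(k, x0 = 0) {
  function(offset) as.integer(stats::runif(1) < logistic_p(offset, k, x0))
}
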