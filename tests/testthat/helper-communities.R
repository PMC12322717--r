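# Shared fixture builders for the test suite.

# A small lognormal community with the default metabolic parameterization.
make_community <- function(S = 10, seed = 42, log_sigma = 2, ...) {
  cfg <- ensemble_config(S = S, n_communities = 1, log_sigma = log_sigma,
                         seed = seed)
  build_interaction_matrix(sample_masses(cfg), alpha = cfg$alpha,
                           a0_rule = cfg$a0_rule, ...)
}

# Slope of log(y) on log(x) by least squares; the independent check used
# against the analytic exponents of the scaling laws.
loglog_slope <- function(x, y) {
  unname(coef(lm(log(y) ~ log(x)))[2])
}
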