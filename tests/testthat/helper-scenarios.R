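# shared fixtures for the test suite; everything is built in code

bpa_scenario <- function() builtin_scenario("bpa15")
rhb_scenario <- function() builtin_scenario("rhodamine20")

# a flat (constant) radical profile: H2O2* == 1 on [0, t_max]
flat_profile <- function(k_prop, c0, t_max = 18000) {
  oh_profile(h2o2_poly(1, t_max_s = t_max), k_prop, c0)
}

# random chain of n pools with rates log-uniform in 10^[9, 11]
random_chain <- function(n = 4L, c0 = 1e-4) {
  list(system = chain_system(paste0("S", seq_len(n)), c0),
       rates = 10^stats::runif(n - 1L, 9, 11))
}

# random cubic H2O2 polynomial shaped like a ramp-and-plateau, positive scale
random_poly <- function(t_max = 18000) {
  cf <- c(stats::runif(1, 0, 0.1), stats::runif(1, 1e-4, 5e-4),
          stats::runif(1, -5e-8, -1e-8), stats::runif(1, 0, 1.5e-12))
  h2o2_poly(cf, t_max_s = t_max)
}
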