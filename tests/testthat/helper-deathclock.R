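# shared helpers for the test suite

# quick dimensionless parameter sets
dp <- function(beta, eta, t_G = 1) expand_dimensionless(beta, eta, t_G = t_G)

# small homotypic well-mixed run
quick_hom_run <- function(beta, eta, n0 = 100L, end_time = 10, seed = 1L,
                          ...) {
  run_wellmixed(wellmixed_config(list(A = dp(beta, eta)), c(A = n0),
                                 end_time = end_time, seed = seed,
                                 init = "staggered", ...))
}

# binomial standard error
binom_se <- function(p, n) sqrt(p * (1 - p) / n)

# direct Monte-Carlo of the death-clock survival condition for a
# prescribed piecewise-constant signal: draw G1 durations, accumulate the
# signal to t*, survive iff the clock stays strictly below the threshold
mc_survival <- function(signal, params, reps = 1e5) {
  tstar <- sample_g1(params, reps)
  tau_at_exit <- signal_cumulative(signal, tstar)
  mean(tau_at_exit < params$death_threshold)
}
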