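# Small shared fixtures for the suite. All data are generated in code;
# sizes are kept modest so individual tests stay fast.

# reduced stopped-flow/quench design for fitting tests
small_design <- function(n_fluor = 80L, n_quench = 30L,
                         concs = c(2.5, 25, 250)) {
  experiment_design(
    fluor_conc = concs,
    fluor_times = exp(seq(log(0.002), log(10), length.out = n_fluor)),
    quench_times = exp(seq(log(0.004), log(60), length.out = n_quench)))
}

# an irreversible-chain rate set (active-only, no dissociation)
chain_rates <- function(k_on = 1, k_inc = 50, k_tra = 100)
  rate_set(k_act = 0, k_inact = 0, k_on = k_on, k_off = 0,
           k_inc = k_inc, k_tra = k_tra, f_inactive0 = 0)

# closed-form POST(t) for the sequential first-order chain
# A -> AN -> PRE -> POST with distinct rates k1, k2, k3
bateman_post <- function(t, k1, k2, k3) {
  1 - (k2 * k3 * exp(-k1 * t) / ((k2 - k1) * (k3 - k1)) +
       k1 * k3 * exp(-k2 * t) / ((k1 - k2) * (k3 - k2)) +
       k1 * k2 * exp(-k3 * t) / ((k1 - k3) * (k2 - k3)))
}

# mean completion time of a 0 -> 1 signal by trapezoidal integration of
# (1 - signal) on a dense log grid
mean_completion_time <- function(times, signal) {
  stats::setNames(sum(diff(times) * (2 - signal[-1] -
                                       signal[-length(signal)]) / 2), NULL)
}

expect_within_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
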