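# Shared fixtures: parameter sets and small synthetic trajectories.

params_for <- function(org) {
  toggle_params(gammaDNF_hat = organization_gamma(org))
}

# A hand-built trajectory object carrying an arbitrary response signal,
# for exercising the interval metrics on known waveforms.
fake_trajectory <- function(times_min, response_vals) {
  states <- cbind(Ra = response_vals, Pa = 0 * response_vals,
                  LRa = 0 * response_vals)
  tr <- ghostmem:::new_trajectory("toggle", times_min * units_per_minute(),
                                  states, 0 * response_vals, NULL,
                                  toggle_params())
  tr
}

# Independent union-length oracle: measure the on-time of a pulse train by
# brute force on a fine time grid (resolution-limited, used at ~1%
# tolerance against the exact interval arithmetic).
union_time_gridded <- function(train, resolution = 0.01) {
  t <- seq(0, train$horizon, by = resolution)
  sum(pulse_indicator(train, t)) * resolution
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
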