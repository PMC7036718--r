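# Stochastic simulation (Stratonovich/Heun), wavelet dominant-frequency
# estimation and the self-organized-criticality run.

test_that("zero noise reduces to the deterministic trajectory", {
  p <- compartment_params()
  det <- simulate_model("compartment", p, step_protocol(10, 15),
                        horizon = 60)
  st <- sde_simulate("compartment", p,
                     noise_spec(sigma = 0, dt = 0.01, dt_max = 0.01),
                     step_protocol(10, 15), horizon = 60, seed = 1)
  expect_lt(max(abs(det$states - st$states)), 1e-6)
})

test_that("runs are reproducible and bounded", {
  p <- params_for("critical")
  ns <- noise_spec(sigma = 0.05, dt = 0.01, adaptive = FALSE)
  a <- sde_simulate("toggle", p, ns, step_protocol(5, 10), horizon = 30,
                    seed = 33)
  b <- sde_simulate("toggle", p, ns, step_protocol(5, 10), horizon = 30,
                    seed = 33)
  expect_identical(a$states, b$states)
  expect_true(all(a$states >= 0 & a$states <= 1))
  expect_false(identical(
    a$states,
    sde_simulate("toggle", p, ns, step_protocol(5, 10), horizon = 30,
                 seed = 34)$states))
})

test_that("stationary fluctuations match linear theory at the high state", {
  # toggle at the bistable high state: for small noise the stationary
  # covariance solves the Lyapunov equation J S + S J' + D D' = 0 of the
  # linearization (independent oracle); empirical variance from long runs
  # must agree within sampling error
  p <- params_for("bistable")
  fp <- toggle_fixed_points(p)
  hi <- fp[fp$stability == "stable" & fp$Ra > 0.1, ]
  x0 <- c(hi$Ra, hi$Pa, 0)
  sigma <- 0.02
  J <- ghostmem:::numeric_jacobian(function(y)
    unname(toggle_derivatives(c(Ra = y[1], Pa = y[2], LRa = y[3]), p,
                              TRUE)), x0)
  g <- sigma * sqrt(pmax(x0 * (1 - x0), 0))
  D <- diag(g^2)
  S <- matrix(solve(kronecker(diag(3), J) + kronecker(J, diag(3)),
                    -as.vector(D)), 3)
  ns <- noise_spec(sigma = sigma, dt = 0.01, adaptive = FALSE)
  v <- replicate(12, {
    tr <- sde_simulate("toggle", p, ns, horizon = 400, dt_out = 0.05,
                       init = x0, amplitude = 0)
    var(tr$states[-(1:400), "Ra"]) # discard the equilibration window
  })
  expect_rel_equal(mean(v), S[1, 1], 0.2)
  # clamping safeguards engage on well under 0.1% of steps here
  tr <- sde_simulate("toggle", p, ns, horizon = 100, dt_out = 0.1,
                     init = x0, seed = 2, amplitude = 0)
  expect_lt(attr(tr, "n_clamped") / attr(tr, "n_steps"), 1e-3)
})

test_that("dominant frequency recovers known signals and flags noise", {
  set.seed(8)
  dt <- 0.05
  t <- seq(0, 400, by = dt)
  f0 <- 0.2
  x <- sin(2 * pi * f0 * t) + rnorm(length(t), 0, 0.3)
  est <- dominant_frequency(x, dt)
  bin <- abs(diff(est$power$frequency[est$power$period >=
                                        est$period][1:2]))
  expect_lt(abs(est$frequency - f0), max(bin, 0.02 * f0) + 1e-9)
  # constant trace is flagged
  expect_warning(cst <- dominant_frequency(rep(1, 600), dt), "constant")
  expect_true(is.na(cst$frequency))
  expect_error(dominant_frequency(rnorm(100), dt), "512")
  # averaging N estimates shrinks the spread roughly as sqrt(N)
  single <- replicate(80, dominant_frequency(rnorm(1024), dt)$frequency)
  avg25 <- replicate(40, mean(replicate(
    25, dominant_frequency(rnorm(1024), dt)$frequency)))
  ratio <- sd(single) / sd(avg25)
  expect_gt(ratio, 2.2) # consistent with sqrt(25) = 5 shrinkage
  expect_lt(ratio, 5 * 2.5)
})

test_that("self-organized recycling maintains post-pulse memory", {
  cp <- compartment_params()
  train <- ghostmem:::new_pulse_train(c(30, 120, 210), 5, 0.2926, 320)
  runs <- self_organized_run(cp, train)
  thr <- 0.25 # post-pulse high-activity threshold on the response scale
  dur <- function(tr, k) { # active time after pulse k, minutes
    t <- tr$times_min
    r <- response(tr)
    on <- t >= train$onsets[k] & t < train$onsets[k] + 90
    sum(r[on] >= thr) * diff(t[1:2])
  }
  d_dyn <- vapply(1:3, function(k) dur(runs$dynamic, k), 1)
  d_fix <- vapply(1:3, function(k) dur(runs$fixed, k), 1)
  # fixed recycling loses the prolongation pulse over pulse
  expect_lt(d_fix[3], 0.7 * d_fix[1])
  # the dynamic law retains it for the later pulses
  expect_gt(d_dyn[3], d_fix[3])
  expect_gt(d_dyn[3], 0.7 * d_dyn[1])
  # kdeg = 0 control: dynamic and fixed recycling are identical
  cp0 <- compartment_params(kdeg = 0)
  runs0 <- self_organized_run(cp0, train)
  expect_equal(runs0$dynamic$states, runs0$fixed$states,
               tolerance = 1e-9)
})
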