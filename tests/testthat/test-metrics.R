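# Activity thresholding, interval metrics and pulse-train ensembles.

test_that("interval extraction handles known waveforms", {
  # flat basal trajectory: no intervals
  flat <- fake_trajectory(seq(0, 100, by = 0.5), rep(0.01, 201))
  iv <- activity_intervals(flat, 0.5)
  expect_identical(nrow(iv), 0L)
  expect_identical(total_active_fraction(iv, 100), 0)
  # square wave crossing the threshold k times
  t <- seq(0, 99, by = 0.1)
  k <- 4L
  sq <- as.numeric((t %% 25) < 10)
  ivk <- activity_intervals(fake_trajectory(t, sq), 0.5)
  expect_identical(nrow(ivk), k)
  expect_equal(total_active_fraction(ivk, 100), k * 10 / 100,
               tolerance = 0.01)
  # full-horizon interval
  one <- activity_intervals(fake_trajectory(t, rep(0.9, length(t))), 0.5)
  expect_identical(nrow(one), 1L)
  expect_equal(total_active_fraction(one), 1, tolerance = 1e-9)
  expect_error(activity_intervals(flat, 1.5), "threshold")
})

test_that("crossing times are refined by interpolation", {
  t <- seq(0, 10, by = 1)
  r <- c(0, 0, 0.2, 0.8, 1, 1, 0.6, 0.2, 0, 0, 0) # crosses 0.5 between
  iv <- activity_intervals(fake_trajectory(t, r), 0.5)
  expect_identical(nrow(iv), 1L)
  expect_equal(iv$start, 2.5, tolerance = 1e-9) # linear interp 0.2 -> 0.8
  expect_equal(iv$end, 6.25, tolerance = 1e-9)  # linear interp 0.6 -> 0.2
})

test_that("interval count never exceeds upward threshold crossings", {
  set.seed(13)
  for (i in 1:20) {
    t <- seq(0, 60, by = 0.2)
    r <- pmin(pmax(cumsum(rnorm(length(t), 0, 0.05)) + 0.5, 0), 1)
    tr <- fake_trajectory(t, r)
    iv <- activity_intervals(tr, 0.5)
    ups <- sum(diff(r >= 0.5) == 1) + (r[1] >= 0.5)
    expect_lte(nrow(iv), ups)
  }
})

test_that("thresholds are the organization-adaptive half-maximum", {
  for (org in c("critical", "monostable")) {
    p <- params_for(org)
    thr <- activity_threshold(p)
    basal <- ghostmem:::toggle_basal_state(p)[["Ra"]]
    act <- activity_threshold(p, frac = 1)
    expect_equal(thr, (basal + act) / 2, tolerance = 1e-9)
    expect_gt(thr, basal)
    expect_lt(thr, act)
  }
  dp <- decay_params(beta = 0.001, RT = 0.8513)
  expect_equal(activity_threshold(dp),
               0.5 * dp$alpha * dp$RT / (dp$alpha + dp$beta),
               tolerance = 1e-12)
})

test_that("small ensembles reproduce the regime fingerprints", {
  # irreversible organization: always exactly one interval ending at the
  # horizon
  ens_b <- ensemble_run(params_for("bistable"), n_trains = 8, seed = 5)
  expect_true(all(ens_b$n_intervals == 1))
  # the interval runs to the end of the horizon for every realization
  p <- params_for("bistable")
  thr <- attr(ens_b, "threshold")
  set.seed(5)
  seeds <- sample.int(.Machine$integer.max - 1, 8)
  tr <- simulate_model("toggle", p,
                       random_pulse_train(12, 5, 480, seed = seeds[1]),
                       init = ghostmem:::toggle_basal_state(p))
  iv <- activity_intervals(tr, thr)
  expect_equal(iv$end[nrow(iv)], 480, tolerance = 1e-6)
  # monostable: many disjoint intervals, fraction near the union on-time
  ens_m <- ensemble_run(params_for("monostable"), n_trains = 8, seed = 5)
  expect_true(all(ens_m$n_intervals >= 7))
  union_frac <- vapply(seeds, function(s) {
    iv <- pulse_intervals(random_pulse_train(12, 5, 480, seed = s))
    sum(iv[, 2] - iv[, 1]) / 480
  }, 1)
  # relaxation broadening makes the response fraction slightly larger
  expect_true(all(ens_m$fraction > union_frac - 0.01))
  expect_lt(mean(ens_m$fraction - union_frac), 0.1)
  # a single-train ensemble is a single point
  e1 <- ensemble_run(params_for("critical"), n_trains = 1, seed = 2)
  expect_identical(nrow(e1), 1L)
  # determinism under the master seed
  e2 <- ensemble_run(params_for("critical"), n_trains = 1, seed = 2)
  expect_identical(e1$fraction, e2$fraction)
})

test_that("ensemble metrics are stable under output-grid refinement", {
  p <- params_for("critical")
  thr <- activity_threshold(p)
  train <- random_pulse_train(12, 5, 480, seed = 77)
  init <- ghostmem:::toggle_basal_state(p)
  tr1 <- simulate_model("toggle", p, train, init = init, dt_out = 0.1)
  tr2 <- simulate_model("toggle", p, train, init = init, dt_out = 0.05)
  iv1 <- activity_intervals(tr1, thr)
  iv2 <- activity_intervals(tr2, thr)
  expect_identical(nrow(iv1), nrow(iv2))
  f1 <- total_active_fraction(iv1, 480)
  f2 <- total_active_fraction(iv2, 480)
  expect_lt(abs(f1 - f2) / f1, 0.005)
})

test_that("decay baseline shows the integration/partitioning trade-off", {
  presets <- decay_presets()[c(1, 5)] # slowest and fastest decay
  suite <- decay_tradeoff_suite(presets, n_trains = 10, seed = 3)
  slow <- suite[[1]]; fast <- suite[[2]]
  # slow decay integrates (large fraction, few intervals)
  expect_lt(mean(slow$n_intervals), mean(fast$n_intervals))
  expect_gt(mean(slow$fraction), mean(fast$fraction))
  # fast decay approaches the train's own on-time fraction
  set.seed(3)
  seeds <- sample.int(.Machine$integer.max - 1, 10)
  union_frac <- vapply(seeds, function(s) {
    iv <- pulse_intervals(random_pulse_train(12, 5, 480, seed = s))
    sum(iv[, 2] - iv[, 1]) / 480
  }, 1)
  expect_lt(mean(abs(fast$fraction - union_frac)), 0.12)
})

test_that("regime fingerprints are robust to 20% threshold shifts", {
  p_b <- params_for("bistable")
  p_m <- params_for("monostable")
  thr_b <- activity_threshold(p_b)
  thr_m <- activity_threshold(p_m)
  for (shift in c(0.8, 1.2)) {
    ens_b <- ensemble_run(p_b, n_trains = 5, seed = 9,
                          threshold = thr_b * shift)
    expect_true(all(ens_b$n_intervals == 1))
    ens_m <- ensemble_run(p_m, n_trains = 5, seed = 9,
                          threshold = thr_m * shift)
    expect_true(all(ens_m$n_intervals >= 7))
  }
})

test_that("a sharp decay model degenerates to the pulse indicator", {
  # activation and decay much faster than the pulse spacing: the response
  # metrics equal those of the indicator itself
  dp <- decay_params(beta = 2, RT = 1, alpha = 20)
  train <- random_pulse_train(6, 5, 240, seed = 11)
  tr <- decay_simulate(dp, train, horizon = 240, dt_out = 0.02)
  iv <- activity_intervals(tr, activity_threshold(dp))
  ivp <- pulse_intervals(train)
  expect_identical(nrow(iv), nrow(ivp))
  expect_equal(total_active_fraction(iv, 240),
               sum(ivp[, 2] - ivp[, 1]) / 240, tolerance = 0.05)
})
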