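# Continuation, fold detection, two-parameter fold tracking, dose-response
# and dynamic-range scans.

test_that("pseudo-arclength continuation resolves the normal-form fold", {
  # dx/dt = mu - x^2: branch x = +/- sqrt(mu), fold at mu = 0
  f <- function(x, mu) mu - x^2
  br <- continue_branch(f, x0 = c(x = 2), p0 = 4, window = c(-1, 4),
                        h0 = 0.05, hmax = 0.2, direction = -1)
  expect_gt(nrow(br), 20)
  expect_identical(length(attr(br, "turning")), 1L)
  ok <- abs(br$param) > 1e-4
  expect_equal(br$x[ok]^2, br$param[ok], tolerance = 1e-6)
  folds <- locate_folds(br, f = f)
  expect_equal(folds$param, 0, tolerance = 1e-8)
  expect_equal(folds$x, 0, tolerance = 1e-6)
})

test_that("toggle branch is S-shaped and matches direct root-finding", {
  p <- toggle_params()
  br <- toggle_branch(p, LRa = 0, window = c(0.5, 5), n = 500)
  expect_identical(length(attr(br, "turning")), 2L)
  # continuation states agree with toggle_fixed_points on a parameter grid
  for (g in seq(1.0, 2.8, length.out = 10)) {
    pg <- toggle_params(gammaDNF_hat = g)
    fp <- toggle_fixed_points(pg)
    for (Ra in fp$Ra)
      expect_equal(ghostmem:::gamma_branch_value(Ra, pg, 0), g,
                   tolerance = 1e-6)
    # number of branch crossings at this parameter equals the FP count
    sgn <- sign(br$param - g)
    expect_identical(sum(abs(diff(sgn)) == 2), nrow(fp))
  }
})

test_that("toggle folds sit at the published saddle-node locations", {
  p <- toggle_params()
  folds <- toggle_folds(p)
  expect_identical(folds$type, c("SN1", "SN2"))
  expect_rel_equal(folds$param[1], 0.8268, 1e-3) # lower fold
  expect_rel_equal(folds$param[2], 2.9521, 1e-3) # upper fold (criticality)
  # fold condition: Jacobian determinant vanishes at both folds
  for (i in 1:2) {
    pp <- p; pp$gammaDNF_hat <- folds$param[i]
    J <- ghostmem:::numeric_jacobian(function(y)
      toggle_derivatives(c(Ra = y[1], Pa = y[2], LRa = 0), pp,
                         ligand_dynamic = FALSE)[1:2],
      c(folds$Ra[i], folds$Pa[i]))
    expect_lt(abs(det(J)), 1e-6)
  }
})

test_that("branch stability changes exactly at the folds", {
  br <- toggle_branch(toggle_params(), n = 800)
  flips <- which(br$stability[-1] != br$stability[-nrow(br)])
  turning <- attr(br, "turning")
  expect_identical(length(flips), 2L)
  expect_true(all(abs(flips - turning) <= 1))
})

test_that("the toggle fold curve closes at a cusp", {
  fc <- toggle_fold_curve(toggle_params(), LRa_max = 0.2, n = 41)
  expect_true(all(c("SN1", "SN2") %in% fc$curve$type))
  # bistable strip narrows with input and ends before LRa_max
  width <- with(fc$curve, tapply(param, LRa, function(z) diff(range(z))))
  expect_lt(fc$cusp[["LRa"]], 0.2)
  expect_gt(fc$cusp[["LRa"]], 0)
  expect_true(all(diff(width) < 1e-9))
})

test_that("dose-response annotates the three memory regimes", {
  dr_rev <- dose_response(params_for("reversible"),
                          seq(0, 0.2, by = 0.005))
  expect_identical(dr_rev$regime, "hysteretic")
  expect_gt(dr_rev$switch_on, dr_rev$switch_off)
  expect_gt(dr_rev$switch_off, 0)

  dr_mono <- dose_response(params_for("monostable"),
                           seq(0, 0.2, by = 0.005))
  expect_identical(dr_mono$regime, "monostable")
  expect_true(all(table(dr_mono$responses$dose) == 1))

  dr_irr <- dose_response(params_for("bistable"), seq(0, 0.2, by = 0.005))
  expect_identical(dr_irr$regime, "irreversible")
  expect_true(is.na(dr_irr$switch_off))
})

test_that("compartment fold and asymptote verify internally", {
  cp <- compartment_params()
  fold <- compartment_fold_rt(cp)
  expect_rel_equal(fold$RT, 1.3499, 0.01)
  # fold condition on the reduced system
  pp <- cp; pp$RT <- fold$RT
  J <- ghostmem:::numeric_jacobian(function(y)
    ghostmem:::compartment_reduced_rhs(y, pp),
    fold$state[c("RaPM", "Pa", "RaE", "RiE")])
  ev <- eigen(J)$values
  expect_lt(min(abs(Re(ev))), 1e-5)

  curve <- compartment_fold_curve(cp, krec_values = 0.042 * c(1, 4, 16))
  expect_true(all(diff(curve$RT) < 0)) # fold RT decreases with krec
  # one-parameter/two-parameter consistency: re-refine each point
  for (i in seq_len(nrow(curve))) {
    pp <- cp; pp$krec <- curve$krec[i]
    expect_equal(compartment_fold_rt(pp)$RT, curve$RT[i],
                 tolerance = 1e-6)
  }
  asym <- compartment_rt_asymptote(cp)
  expect_gt(asym$RT_asymp, 1)
  expect_lt(asym$RT_asymp, min(curve$RT))
})

test_that("generic continuation reproduces the compartment fold", {
  cp <- compartment_params(LT = 0)
  f <- function(x, RT) {
    pp <- cp; pp$RT <- RT
    ghostmem:::compartment_reduced_rhs(x, pp)
  }
  start <- compartment_fixed_points(compartment_params(RT = 1.6, LT = 0))
  hi <- start[which.max(start$RaPM), ]
  br <- continue_branch(f, x0 = unlist(hi[c("RaPM", "Pa", "RaE", "RiE")]),
                        p0 = 1.6, window = c(1.25, 1.8), h0 = 0.02,
                        hmax = 0.05, direction = -1, max_points = 400)
  folds <- locate_folds(br, f = f)
  expect_gt(nrow(folds), 0)
  expect_equal(folds$param[1], compartment_fold_rt(cp)$RT,
               tolerance = 1e-6)
})

test_that("amplitude gain peaks at the saddle-node organization", {
  p <- toggle_params()
  gammas <- seq(2.6, 4.6, by = 0.05)
  scan <- dynamic_range_scan(p, gammas, settle_min = 400)
  fold <- toggle_folds(p)$param[2]
  peak <- scan$gamma[which.max(scan$gain)]
  expect_lt(abs(peak - fold), 0.051) # within one grid step of the fold
  # gain decreases into the monostable regime, strictly below the peak
  expect_lt(scan$gain[length(gammas)], max(scan$gain))
  expect_true(all(diff(scan$gain[gammas > fold + 0.1]) < 1e-9))
  # zero activating input gives zero gain
  scan0 <- dynamic_range_scan(p, c(2.8, 3.5), input = 0)
  expect_equal(scan0$gain, c(0, 0), tolerance = 1e-12)
})
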