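# Toggle switch, compartment model and decay baseline: right-hand sides,
# fixed points, conservation, and limit equivalences.

test_that("toggle derivatives reproduce hand-evaluated examples", {
  p <- toggle_params(gammaDNF_hat = 2.957)
  # basal fixed point: Ra = 0 forces stationary Pa = 1/(1+k21) = 2/3
  d0 <- toggle_derivatives(c(Ra = 0, Pa = 1 / 1.5, LRa = 0),
                           toggle_params(gammaDNF_hat = 2.957,
                                         alpha1 = 0), TRUE)
  expect_equal(unname(d0), c(0, 0, 0), tolerance = 1e-12)
  # stationary Pa at Ra = 0 for any reactivity
  for (g in c(0.5, 2.957, 10)) {
    pg <- toggle_params(gammaDNF_hat = g)
    dP <- toggle_derivatives(c(Ra = 0, Pa = 1 / (1 + pg$k21), LRa = 0),
                             pg, FALSE)[["dPa"]]
    expect_equal(dP, 0, tolerance = 1e-14)
  }
  # hand evaluation of dRa at (0.5, 0.1), gamma 2.957:
  # 0.8 * (0.5*(0.0017*0.5 + 0.3*0.5) - 2.957*0.1*0.5) = -0.05794
  d <- toggle_derivatives(c(Ra = 0.5, Pa = 0.1, LRa = 0), p, FALSE)
  expect_equal(d[["dRa"]],
               0.8 * (0.5 * (0.0017 * 0.5 + 0.3 * 0.5) -
                        2.957 * 0.1 * 0.5),
               tolerance = 1e-12)
  expect_error(toggle_derivatives(c(Ra = 1.5, Pa = 0.1, LRa = 0), p),
               "outside")
})

test_that("R and C++ right-hand sides agree on random admissible states", {
  set.seed(41)
  p <- toggle_params(gammaDNF_hat = 3.1, LT = 0.7)
  cp <- compartment_params(LT = 0.25)
  for (i in 1:25) {
    s <- runif(3, 0, 0.33)
    dR <- toggle_derivatives(c(Ra = s[1], Pa = s[2], LRa = s[3]), p, TRUE)
    dC <- ghostmem:::.model_rhs_cpp(0L, as_param_vector(p), s, p$LT)
    expect_equal(unname(dR), unname(dC), tolerance = 1e-13)

    x <- runif(7); x <- 0.999 * x / sum(x)
    names(x) <- c("RaPM", "RiPM", "Pa", "LRaPM", "RaE", "RiE", "LRiE")
    dR2 <- compartment_derivatives(x, cp, dynamic_krec = TRUE)
    dC2 <- ghostmem:::.model_rhs_cpp(
      2L, as_param_vector(cp, dynamic_krec = TRUE), unname(x), cp$LT)
    expect_equal(unname(dR2), unname(dC2), tolerance = 1e-13)
  }
})

test_that("fixed-point count matches the published organizations", {
  fp_b <- toggle_fixed_points(params_for("bistable"))
  expect_identical(sum(fp_b$stability == "stable"), 2L)
  expect_identical(sum(fp_b$stability == "saddle"), 1L)
  fp_m <- toggle_fixed_points(params_for("monostable"))
  expect_identical(nrow(fp_m), 1L)
  expect_identical(fp_m$stability, "stable")
})

test_that("fixed points coincide with roots of the closed-form branch", {
  p <- params_for("reversible")
  fp <- toggle_fixed_points(p, LRa = 0)
  for (Ra in fp$Ra) # branch relation gamma(Ra) = gammaDNF_hat at a root
    expect_equal(ghostmem:::gamma_branch_value(Ra, p, 0), p$gammaDNF_hat,
                 tolerance = 1e-8)
})

test_that("steady states are invariant under kR and k1 rescaling", {
  base <- toggle_fixed_points(params_for("critical"))
  for (f in c(0.1, 7)) {
    fp <- toggle_fixed_points(toggle_params(gammaDNF_hat = 2.957,
                                            kR = 0.8 * f, k1 = 0.01 * f))
    expect_equal(fp$Ra, base$Ra, tolerance = 1e-9)
    expect_equal(fp$Pa, base$Pa, tolerance = 1e-9)
  }
})

test_that("toggle trajectories conserve mass and reach fixed points", {
  p <- params_for("critical")
  tr <- simulate_model("toggle", p, step_protocol(10, 15), horizon = 200)
  # Ri = 1 - Ra - LRa must stay a valid fraction along the trajectory
  resid <- tr$states[, "Ra"] + tr$states[, "LRa"]
  expect_true(all(resid >= -1e-9 & resid <= 1 + 1e-9))
  # zero input from basal init stays at the basal fixed point
  tr0 <- simulate_model("toggle", p, NULL, horizon = 60)
  expect_lt(diff(range(response(tr0))), 1e-7)
  # long-term memory at gamma 2.5: response stays high after the pulse
  trb <- simulate_model("toggle", params_for("bistable"),
                        step_protocol(10, 15), horizon = 200)
  expect_gt(tail(response(trb), 1), 0.5)
  # monostable: response returns to basal promptly
  trm <- simulate_model("toggle", params_for("monostable"),
                        step_protocol(10, 15), horizon = 200)
  expect_lt(tail(response(trm), 1), 0.05)
})

test_that("compartment derivatives conserve total mass exactly", {
  set.seed(7)
  cp <- compartment_params(LT = 0.29)
  for (i in 1:20) {
    x <- runif(7); x <- 0.999 * x / sum(x)
    names(x) <- c("RaPM", "RiPM", "Pa", "LRaPM", "RaE", "RiE", "LRiE")
    d <- compartment_derivatives(x, cp, dynamic_krec = (i %% 2 == 0))
    expect_equal(sum(d[names(d) != "Pa"]), 0, tolerance = 1e-15)
  }
  # no ligand, no bound species: bound-species derivatives vanish
  x0 <- c(RaPM = 0.1, RiPM = 0.5, Pa = 0.4, LRaPM = 0, RaE = 0.2,
          RiE = 0.2, LRiE = 0)
  d0 <- compartment_derivatives(x0, compartment_params(LT = 0))
  expect_identical(unname(d0[c("LRaPM", "LRiE")]), c(0, 0))
})

test_that("compartment trajectories conserve mass to 1e-9", {
  cp <- compartment_params(LT = 0)
  tr <- simulate_model("compartment", cp, step_protocol(10, 15,
                                                        amplitude = 0.2926),
                       horizon = 300)
  expect_lt(max(abs(rowSums(tr$states[, colnames(tr$states) != "Pa"]) - 1)),
            1e-9)
})

test_that("dynamic recycling multiplier behaves as specified", {
  cp <- compartment_params()
  expect_equal(dynamic_recycling_rate(0, cp), cp$krec, tolerance = 1e-14)
  # cap binds exactly where RT (1 - LRiE) reaches the asymptote
  lri_cap <- 1 - cp$RT_asymp / cp$RT # ~ 0.1955
  expect_equal(lri_cap, 0.1955, tolerance = 1e-3)
  expect_equal(dynamic_recycling_rate(lri_cap + 1e-6, cp),
               cp$krec * cp$sat, tolerance = 1e-10)
  # multiplier never exceeds the saturation level
  lr <- seq(0, 0.99, by = 0.01)
  expect_true(all(dynamic_recycling_rate(lr, cp) <=
                    cp$krec * cp$sat + 1e-12))
})

test_that("compartment model has a stable basal state at zero ligand", {
  fp <- compartment_fixed_points(compartment_params(LT = 0))
  basal <- fp[which.min(fp$RaPM), ]
  expect_identical(basal$stability, "stable")
  expect_lt(basal$RaPM, 0.01)
  # the root satisfies the full right-hand side
  st <- unlist(basal[c("RaPM", "RiPM", "Pa", "LRaPM", "RaE", "RiE",
                       "LRiE")])
  d <- compartment_derivatives(st, compartment_params(LT = 0))
  expect_lt(max(abs(d)), 1e-9)
})

test_that("trafficking-free compartment model collapses onto the toggle", {
  # kdeg = kin = krec-flux = 0 and the extra phosphatases off: membrane
  # fixed points must match the toggle branch with gamma_hat = gDNF*PT/RT
  # and beta_hat = betaDNF*RT (unit kR absorbed in RT)
  RT <- 1
  cp <- compartment_params(RT = RT, kin = 0, gammaNF = 0, gammaNR = 0,
                           kdeg = 0, LT = 0)
  tp <- toggle_params(gammaDNF_hat = cp$gammaDNF * cp$PDNFT / RT,
                      betaDNF_hat = cp$betaDNF * RT)
  fp_t <- toggle_fixed_points(tp)
  f <- function(RaPM) {
    Pa <- 1 / (1 + cp$k21 + cp$betaDNF * RT * RaPM)
    RT * (1 - RaPM) * (cp$alpha1 * (1 - RaPM) + cp$alpha2 * RaPM) -
      cp$gammaDNF * cp$PDNFT * Pa * RaPM
  }
  for (Ra in fp_t$Ra) expect_lt(abs(f(Ra)), 1e-10)
})

test_that("decay model matches its closed forms", {
  dp <- decay_params(beta = 0.001, RT = 0.8513)
  # constant input steady state alpha RT / (alpha + beta)
  tr <- decay_simulate(dp, new_pulse_train(0, 600, 1, 600), horizon = 600)
  expect_equal(tail(response(tr), 1),
               dp$alpha * dp$RT / (dp$alpha + dp$beta), tolerance = 1e-6)
  # free decay Ra(t) = Ra0 exp(-beta t)
  tr2 <- simulate_model("decay", dp, NULL, init = c(Ra = 0.5),
                        horizon = 60, dt_out = 10)
  expect_equal(response(tr2),
               0.5 * exp(-dp$beta * tr2$times), tolerance = 1e-8)
})

test_that("the five decay presets share the critical activated amplitude", {
  amps <- vapply(decay_presets(), function(p)
    p$alpha * p$RT / (p$alpha + p$beta), 1)
  expect_lt(diff(range(amps)) / mean(amps), 0.01)
  # cross-check against the criticality model's activated response
  act <- ghostmem:::toggle_activated_amplitude(params_for("critical"))
  expect_rel_equal(mean(amps), act, 0.01)
})
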