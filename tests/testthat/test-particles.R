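# Particle-based reaction-diffusion simulation, R0 estimation and
# macrostate classification.

test_that("microscopic parameter invariants are enforced", {
  mp <- micro_params()
  # detection guarantee with the published defaults: 17.9 nm <= 20 nm
  expect_lte(4 * sqrt(2 * mp$D * mp$dt), mp$sigma)
  expect_true(all(mp$rates * mp$dt <= 1))
  expect_error(micro_params(D = 10), "detection")
  expect_error(micro_params(dt = 2e-3), "probability|detection")
  expect_equal(mp$u, 1 / (pi * 0.02^2), tolerance = 1e-12)
  expect_identical(mp$nR, 375L)
  expect_identical(mp$nP, 500L)
})

test_that("a frozen world does not change and runs reproduce under seed", {
  mp <- micro_params(gamma_mult = 0, alpha1_mult = 0, alpha2_mult = 0,
                     beta_mult = 0, k1 = 0, k2 = 0, side = 1)
  mp$D <- 0 # no diffusion either
  sim <- simulate_particles(mp, horizon = 0.05, seed = 1,
                            snapshot_every = 0.01)
  expect_true(all(sim$counts$nRa == sim$counts$nRa[1]))
  expect_true(all(sim$counts$nPa == sim$counts$nPa[1]))
  s1 <- sim$snapshots[[1]]; s2 <- sim$snapshots[[length(sim$snapshots)]]
  expect_identical(s1, s2)
  # molecule counts per species are constant and positions stay in domain
  expect_identical(sum(s1[, 3] == 1), mp$nR)
  expect_identical(sum(s1[, 3] == 2), mp$nP)
  expect_true(all(s1[, 1] >= 0 & s1[, 1] < mp$side))
  # seed reproducibility of a live run
  mp2 <- micro_params(side = 1)
  a <- simulate_particles(mp2, horizon = 0.2, seed = 42, init = "high")
  b <- simulate_particles(mp2, horizon = 0.2, seed = 42, init = "high")
  expect_identical(a$counts, b$counts)
  expect_identical(a$deactivations, b$deactivations)
})

test_that("event logs are internally consistent", {
  mp <- micro_params(side = 1.5)
  sim <- simulate_particles(mp, horizon = 1, seed = 9, init = "high")
  de <- sim$deactivations
  ac <- sim$activations
  expect_true(all(de$offspring >= 0))
  expect_true(all(de$lifetime > 0))
  expect_true(all(de$id >= 0 & de$id < mp$nR))
  expect_true(all(ac$activated >= 0 & ac$activated < mp$nR))
  expect_true(all(ac$activator >= -1 & ac$activator < mp$nR))
  # total offspring credited never exceeds total activations
  expect_lte(sum(de$offspring), nrow(ac) + mp$nR)
})

test_that("analytic R0 identities hold (threshold and fixed point)", {
  # doubling the reactivity halves the transmission potential
  expect_equal(analytic_R0(0.2, 0.5, gamma = 2),
               analytic_R0(0.2, 0.5, gamma = 1) / 2, tolerance = 1e-14)
  expect_error(analytic_R0(0.2, 0), "positive")
  p0 <- toggle_params(gammaDNF_hat = 2.0, alpha1 = 0)
  # basal form: R0 = alpha2 (k1+k2) / (gamma k1) in hatted units
  base <- analytic_R0(0, 1 / (1 + p0$k21), alpha2 = p0$alpha2,
                      gamma = p0$gammaDNF_hat)
  expect_equal(base, p0$alpha2 * (1 + p0$k21) / p0$gammaDNF_hat,
               tolerance = 1e-12)
  # at the nonzero fixed point (autonomous activation neglected) R0 = 1
  fp <- toggle_fixed_points(p0)
  hi <- fp[fp$stability == "stable" & fp$Ra > 0.1, ]
  expect_identical(nrow(hi), 1L)
  expect_equal(analytic_R0(hi$Ra, hi$Pa, alpha2 = p0$alpha2,
                           gamma = p0$gammaDNF_hat), 1,
               tolerance = 1e-9)
  # basal-state stability flips exactly at R0 = 1 across the reactivity
  # sweep: stable iff R0 < 1
  for (g in c(0.2, 0.4, 0.44, 0.46, 0.6, 2)) {
    pg <- toggle_params(gammaDNF_hat = g, alpha1 = 0)
    J <- ghostmem:::numeric_jacobian(function(y)
      toggle_derivatives(c(Ra = y[1], Pa = y[2], LRa = 0), pg,
                         ligand_dynamic = FALSE)[1:2],
      c(0, 1 / (1 + pg$k21)))
    stable <- all(Re(eigen(J)$values) < 0)
    r0 <- analytic_R0(0, 1 / (1 + pg$k21), alpha2 = pg$alpha2, gamma = g)
    expect_identical(stable, r0 < 1)
  }
})

test_that("R0 estimation handles trivial and windowed logs", {
  de <- data.frame(time = c(0.1, 0.15, 0.3), offspring = c(0, 0, 2))
  est <- estimate_R0(de, t_center = 0.125, window = 0.1)
  expect_identical(est$n, 2L)
  expect_identical(est$R0, 0)
  est_all <- estimate_R0(de, t_center = 0.2, window = 0.4)
  expect_equal(est_all$R0, 2 / 3, tolerance = 1e-12)
  expect_warning(est0 <- estimate_R0(de[0, ]), "no completed")
  expect_true(is.na(est0$R0))
})

test_that("macrostate classification recovers known mixtures", {
  set.seed(5)
  a <- cbind(rnorm(300, 0.10, 0.02), rnorm(300, 0.90, 0.02))
  b <- cbind(rnorm(300, 0.60, 0.03), rnorm(300, 0.30, 0.03))
  fit <- classify_macrostates(rbind(a, b))
  expect_false(fit$degenerate)
  expect_equal(fit$centroids[1, ], c(0.10, 0.90), tolerance = 0.02)
  expect_equal(fit$centroids[2, ], c(0.60, 0.30), tolerance = 0.02)
  # degenerate path: identical samples
  expect_warning(
    deg <- classify_macrostates(matrix(0.3, 200, 2)), "degenerate")
  expect_identical(nrow(deg$centroids), 1L)
  expect_error(classify_macrostates(a[1:50, ]), "100")
})

test_that("quadratic fold profiles fit exact and branch data", {
  # exact quadratic input: zero residual, exact vertex
  Ra <- seq(0.1, 0.8, by = 0.1)
  g <- 3 - 2 * (Ra - 0.45)^2
  fit <- fit_fold_profile(g, Ra)
  expect_lt(1 - fit$r_squared, 1e-12)
  expect_equal(fit$fold_gamma, 3, tolerance = 1e-9)
  expect_equal(fit$fold_Ra, 0.45, tolerance = 1e-9)
  expect_warning(fit_fold_profile(c(1, 2, 3), c(0.5, 0.5, 0.5)), "rank")
  # the macroscopic closed-form branch is approximately quadratic near
  # its fold
  p <- toggle_params()
  Ra2 <- seq(0.25, 0.7, length.out = 10)
  fit2 <- fit_fold_profile(ghostmem:::gamma_branch_value(Ra2, p, 0), Ra2)
  expect_gt(fit2$r_squared, 0.95)
  expect_rel_equal(fit2$fold_gamma, toggle_folds(p)$param[2], 0.02)
})
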