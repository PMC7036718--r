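# Single-molecule reaction-diffusion simulation (Doi method) on a
# periodic 2D membrane, with basic-reproduction-number estimation and
# macrostate classification.

#' Microscopic simulation parameters
#'
#' Parameters of the particle-based toggle-switch simulation.  Bimolecular
#' rates are stated as multipliers of the normalization unit
#' `u = 1/(pi sigma^2)` (the inverse interaction-disc area), so the sweep
#' positions of the published regimes -- bistable 4.55, critical 4.95,
#' monostable 6 -- are well-defined relative to each other.  The published
#' multipliers are 0.0017 (autonomous), 0.3 (autocatalytic) and 9
#' (phosphatase inhibition); unimolecular phosphatase rates are 5 and
#' 0.5 per second.
#'
#' @param gamma_mult phosphatase reactivity multiplier (swept in `[0, 9]`).
#' @param side domain side length in micrometres (2.5 or 3.5).
#' @param D diffusion coefficient of both species, um^2/s.
#' @param rho molecule radius in micrometres; the interaction radius is
#'   `sigma = 2 rho`.
#' @param dt time step in seconds.
#' @param density_R,density_P molecules per square micrometre.
#' @param k1,k2 phosphatase activation/deactivation rates (1/s).
#' @param alpha1_mult,alpha2_mult,beta_mult bimolecular rate multipliers.
#' @return A `micro_params` object; rates in 1/s are in `$rates`.
#' @export
micro_params <- function(gamma_mult = 4.95, side = 2.5, D = 0.1,
                         rho = 0.01, dt = 1e-4, density_R = 60,
                         density_P = 80, k1 = 5, k2 = 0.5,
                         alpha1_mult = 0.0017, alpha2_mult = 0.3,
                         beta_mult = 9) {
  sigma <- 2 * rho
  u <- 1 / (pi * sigma^2)
  rates <- c(alpha1 = alpha1_mult * u, alpha2 = alpha2_mult * u,
             beta = beta_mult * u, gamma = gamma_mult * u, k1 = k1,
             k2 = k2)
  if (4 * sqrt(2 * D * dt) > sigma)
    stop("detection guarantee violated: need 4*sqrt(2 D dt) <= sigma")
  if (any(rates * dt > 1))
    stop("a per-step reaction probability exceeds 1")
  structure(list(gamma_mult = gamma_mult, side = side, D = D, rho = rho,
                 sigma = sigma, dt = dt, density_R = density_R,
                 density_P = density_P, u = u, rates = rates,
                 nR = as.integer(round(density_R * side^2)),
                 nP = as.integer(round(density_P * side^2)),
                 alpha1_mult = alpha1_mult, alpha2_mult = alpha2_mult,
                 beta_mult = beta_mult),
            class = "micro_params")
}

#' Run a particle-based reaction-diffusion simulation
#'
#' Simulates receptor and phosphatase molecules diffusing on a periodic
#' square membrane; bimolecular state transitions follow the Doi rule
#' (probability `1 - (1 - g dt)^n` over the `n` eligible partners within
#' the interaction radius), unimolecular transitions fire with probability
#' `k dt`.  Activation events record which active receptor propagated its
#' state, enabling basic-reproduction-number estimation.
#'
#' @param mp [micro_params()].
#' @param horizon simulated time in seconds.
#' @param init `"basal"` (all receptors inactive) or `"high"` (90%
#'   active).
#' @param record_every recording interval of the activity time series, s.
#' @param log_window two times (s) bounding event logging (default: whole
#'   run).
#' @param snapshot_every optional snapshot interval, s (0 = none).
#' @param seed optional RNG seed.
#' @return A `particle_sim`: list with `counts` (data frame `time`, `nRa`,
#'   `nPa`, `fRa`, `fPa`), `activations`, `deactivations`, `params`.
#' @export
simulate_particles <- function(mp, horizon = 10, init = c("basal", "high"),
                               record_every = 0.01, log_window = NULL,
                               snapshot_every = 0, seed = NULL) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(log_window)) log_window <- c(0, horizon)
  nsteps <- round(horizon / mp$dt)
  fracRa0 <- if (init == "high") 0.9 else 0
  ktot <- mp$rates[["k1"]] + mp$rates[["k2"]]
  fracPa0 <- if (ktot > 0) mp$rates[["k1"]] / ktot else 0
  res <- .particle_sim_cpp(mp$nR, mp$nP, mp$side, mp$D, mp$sigma, mp$dt,
                           nsteps, mp$rates[["alpha1"]],
                           mp$rates[["alpha2"]], mp$rates[["beta"]],
                           mp$rates[["gamma"]], mp$rates[["k1"]],
                           mp$rates[["k2"]], fracRa0, fracPa0,
                           max(1L, round(record_every / mp$dt)),
                           log_window[1], log_window[2],
                           if (snapshot_every > 0)
                             round(snapshot_every / mp$dt) else 0L)
  counts <- as.data.frame(res$counts)
  names(counts) <- c("time", "nRa", "nPa")
  counts$fRa <- counts$nRa / mp$nR
  counts$fPa <- counts$nPa / mp$nP
  structure(list(counts = counts, activations = res$activations,
                 deactivations = res$deactivations,
                 snapshots = res$snapshots, params = mp, init = init,
                 horizon = horizon),
            class = "particle_sim")
}

#' @export
print.particle_sim <- function(x, ...) {
  cat(sprintf(
    "Particle simulation: %d R + %d P on %.1f um side, %.2f s horizon\n",
    x$params$nR, x$params$nP, x$params$side, x$horizon))
  invisible(x)
}

#' Basic reproduction number from a particle event log
#'
#' For every receptor deactivation inside the averaging window, the number
#' of molecules that receptor activated during its just-completed active
#' lifetime is its offspring count; the estimate is the mean (and SD) of
#' those counts.
#'
#' @param sim a `particle_sim`, or a deactivation data frame with columns
#'   `time` and `offspring`.
#' @param t_center centre of the averaging window, s (default: the
#'   midpoint of the logged range).
#' @param window window length, s (about 0.2 in the published analysis).
#' @return List `R0`, `sd`, `n` (events in the window).
#' @export
estimate_R0 <- function(sim, t_center = NULL, window = 0.2) {
  de <- if (inherits(sim, "particle_sim")) sim$deactivations else sim
  if (!nrow(de)) {
    warning("no completed activation lifetimes in the log")
    return(list(R0 = NA_real_, sd = NA_real_, n = 0L))
  }
  if (is.null(t_center)) t_center <- mean(range(de$time))
  sel <- abs(de$time - t_center) <= window / 2
  if (!any(sel)) {
    warning("no deactivations inside the averaging window")
    return(list(R0 = NA_real_, sd = NA_real_, n = 0L))
  }
  x <- de$offspring[sel]
  list(R0 = mean(x), sd = sd(x), n = length(x))
}

#' Analytic activation transmission potential
#'
#' The basic reproduction number at a macroscopic state: the product of
#' the average molecular activation rate `alpha2 RT (1 - Ra)` and the
#' average active lifetime `1 / (gamma PT Pa)`, i.e.
#' `R0 = alpha2 RT (1 - Ra) / (gamma PT Pa)`.  At the basal state
#' (`Ra = 0`, `Pa = k1/(k1+k2)`) this reduces to
#' `alpha2 RT (k1+k2) / (gamma PT k1)`, and `R0 = 1` holds exactly at the
#' nonzero fixed point of the toggle with autonomous activation neglected.
#' For microscopic parameters use the species densities for `RT`, `PT`
#' and the multipliers for `alpha2`, `gamma` (the normalization unit
#' cancels).
#'
#' @param Ra,Pa active receptor and phosphatase fractions; `Pa` must be
#'   positive.
#' @param alpha2 autocatalytic activation constant.
#' @param gamma phosphatase specific reactivity.
#' @param RT,PT total receptor and phosphatase levels.
#' @return The transmission potential.
#' @export
analytic_R0 <- function(Ra, Pa, alpha2 = 0.3, gamma = 1, RT = 1, PT = 1) {
  if (any(Pa <= 0)) stop("Pa must be positive")
  alpha2 * RT * (1 - Ra) / (gamma * PT * Pa)
}

#' @rdname analytic_R0
#' @param mp [micro_params()].
#' @export
micro_analytic_R0 <- function(mp, Ra, Pa) {
  analytic_R0(Ra, Pa, alpha2 = mp$alpha2_mult, gamma = mp$gamma_mult,
              RT = mp$density_R, PT = mp$density_P)
}

#' Classify basal/high macrostates from phase-space samples
#'
#' Fits a two-component Gaussian mixture to `(Ra, Pa)` fraction samples,
#' then iteratively prunes points beyond the 90th percentile of their
#' component's Mahalanobis distance and refits until the assignment set
#' stabilizes.  Degenerate (effectively single-cluster) data yield one
#' centroid with a warning.
#'
#' @param samples numeric matrix with two columns (e.g. `fRa`, `fPa`).
#' @param max_iter pruning iteration cap.
#' @param percentile pruning cut-off.
#' @return List `centroids` (one row per component, ordered by the first
#'   column), `assignment`, `kept`, `degenerate`.
#' @export
classify_macrostates <- function(samples, max_iter = 20,
                                 percentile = 0.9) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 100) stop("need at least 100 phase samples")
  spread <- apply(samples, 2, function(z) diff(range(z)))
  degenerate_out <- function() {
    warning("degenerate (single-cluster) samples; returning one centroid")
    list(centroids = matrix(colMeans(samples), 1), assignment = NULL,
         kept = seq_len(nrow(samples)), degenerate = TRUE)
  }
  if (all(spread < 1e-12)) return(degenerate_out())
  km <- kmeans(samples, centers = 2, nstart = 5)
  if (min(km$size) < 5 || km$betweenss / km$totss < 0.5)
    return(degenerate_out())
  # fit on the retained points, but re-derive the retained set from the
  # full sample each round (distance cut-off at the given percentile per
  # component), so the iteration has a fixed point and "until
  # convergence" means: the retained set stops changing
  kept <- seq_len(nrow(samples))
  for (it in seq_len(max_iter)) {
    fit <- gmm2_em(samples[kept, , drop = FALSE])
    if (is.null(fit)) return(degenerate_out())
    d_all <- sapply(1:2, function(k)
      mahalanobis(samples, fit$mu[k, ], fit$Sigma[[k]]))
    assign_all <- max.col(-d_all)
    dist_own <- d_all[cbind(seq_len(nrow(samples)), assign_all)]
    cut <- vapply(1:2, function(k)
      quantile(dist_own[assign_all == k], percentile, names = FALSE), 1)
    new_kept <- which(dist_own <= cut[assign_all])
    if (identical(new_kept, kept)) break
    kept <- new_kept
  }
  fit <- gmm2_em(samples[kept, , drop = FALSE])
  ord <- order(fit$mu[, 1])
  list(centroids = fit$mu[ord, , drop = FALSE],
       assignment = ord[max.col(fit$resp)], kept = kept,
       degenerate = FALSE)
}

# Two-component Gaussian-mixture EM with full covariances (small, local
# implementation; regularized to avoid singular covariances).
gmm2_em <- function(x, max_iter = 200, tol = 1e-8) {
  n <- nrow(x); d <- ncol(x)
  km <- tryCatch(kmeans(x, 2, nstart = 3), error = function(e) NULL)
  if (is.null(km) || min(km$size) < 3) return(NULL)
  mu <- km$centers
  Sigma <- lapply(1:2, function(k) {
    s <- cov(x[km$cluster == k, , drop = FALSE])
    s + diag(1e-8, d)
  })
  pi_k <- km$size / n
  ll_old <- -Inf
  dens <- function(mu_k, S) {
    cS <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(cS)) return(NULL)
    z <- forwardsolve(t(cS), t(x) - mu_k)
    exp(-0.5 * colSums(z^2)) / (2 * pi * prod(diag(cS)))
  }
  for (it in seq_len(max_iter)) {
    f1 <- dens(mu[1, ], Sigma[[1]]); f2 <- dens(mu[2, ], Sigma[[2]])
    if (is.null(f1) || is.null(f2)) return(NULL)
    num <- cbind(pi_k[1] * f1, pi_k[2] * f2)
    tot <- rowSums(num)
    if (any(tot <= 0)) tot[tot <= 0] <- 1e-300
    resp <- num / tot
    ll <- sum(log(tot))
    nk <- colSums(resp)
    if (any(nk < 3)) return(NULL)
    for (k in 1:2) {
      mu[k, ] <- colSums(resp[, k] * x) / nk[k]
      xc <- sweep(x, 2, mu[k, ])
      Sigma[[k]] <- crossprod(xc * sqrt(resp[, k])) / nk[k] +
        diag(1e-8, d)
    }
    pi_k <- nk / n
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sigma, pi = pi_k, resp = resp, loglik = ll)
}

#' Quadratic bifurcation profile through estimated activity states
#'
#' Least-squares quadratic `gamma(Ra) = c0 + c1 Ra + c2 Ra^2` through
#' (reactivity, activity-state) points, mirroring the approximately
#' quadratic dependence of the reactivity on the high-activity state.  The
#' fitted fold is the vertex of the parabola.
#'
#' @param gamma reactivity values (sweep multipliers).
#' @param Ra matching activity-state estimates.
#' @return List `coef`, `r_squared`, `fold_gamma`, `fold_Ra`,
#'   `rank_deficient`.
#' @export
fit_fold_profile <- function(gamma, Ra) {
  if (length(gamma) < 3) stop("need at least 3 points")
  fit <- lm(gamma ~ Ra + I(Ra^2))
  co <- coef(fit)
  rank_def <- any(is.na(co)) || fit$rank < 3
  if (rank_def) warning("rank-deficient quadratic fit")
  r2 <- if (rank_def) NA_real_ else
    1 - sum(residuals(fit)^2) / sum((gamma - mean(gamma))^2)
  fold_Ra <- if (rank_def || co[3] == 0) NA_real_ else -co[2] / (2 * co[3])
  fold_gamma <- if (is.na(fold_Ra)) NA_real_ else
    co[1] + co[2] * fold_Ra + co[3] * fold_Ra^2
  list(coef = co, r_squared = r2, fold_gamma = unname(fold_gamma),
       fold_Ra = unname(fold_Ra), rank_deficient = rank_def)
}
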