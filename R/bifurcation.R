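# Steady-state continuation and fold (saddle-node) analysis, standing in
# for an AUTO-style continuation tool.  The toggle switch admits an exact
# parametric branch (parameterized by Ra), used wherever possible; the
# compartment model is handled by generic pseudo-arclength continuation on
# its reduced zero-ligand system plus a scalar fold refiner.

new_branch <- function(df, param_name, model = NA_character_) {
  stopifnot(all(c("param", "stability") %in% names(df)))
  turning <- which(diff(sign(diff(df$param))) != 0) + 1
  structure(df, class = c("ghost_branch", "data.frame"),
            param_name = param_name, model = model, turning = turning)
}

#' Steady-state branch of the toggle switch (closed form)
#'
#' The full steady-state branch of the toggle at constant input, obtained
#' from the exact parameterization by `Ra`: substituting the stationary
#' phosphatase fraction into `dRa/dt = 0` gives the specific reactivity as
#' `gamma(Ra) = (1-Ra)(a1(1-Ra)+a2 Ra+a3 LRa)(1+k21+beta(Ra+LRa))/Ra`.
#' The branch is S-shaped in the bistable regime, with turning points at
#' the saddle-node bifurcations.
#'
#' @param params [toggle_params()].
#' @param LRa constant ligand-bound input.
#' @param window range of `gammaDNF_hat` to keep.
#' @param n number of `Ra` samples along the branch.
#' @return A `ghost_branch` data frame with columns `param`
#'   (`gammaDNF_hat`), `Ra`, `Pa`, `response`, `stability`.
#' @export
toggle_branch <- function(params, LRa = 0, window = c(0.5, 5), n = 600) {
  Ra <- exp(seq(log(1e-4), log(1 - 1e-4 - LRa), length.out = n))
  g <- gamma_branch_value(Ra, params, LRa)
  keep <- g >= window[1] & g <= window[2]
  Ra <- Ra[keep]; g <- g[keep]
  stab <- vapply(seq_along(Ra), function(i) {
    pp <- params; pp$gammaDNF_hat <- g[i]
    Pa <- toggle_Pa_stationary(pp, Ra[i] + LRa)
    J <- numeric_jacobian(function(y)
      toggle_derivatives(c(Ra = y[1], Pa = y[2], LRa = LRa), pp,
                         ligand_dynamic = FALSE)[1:2], c(Ra[i], Pa))
    classify_stability(eigen(J)$values)
  }, "")
  new_branch(data.frame(param = g, Ra = Ra,
                        Pa = toggle_Pa_stationary(params, Ra + LRa),
                        response = Ra + LRa, stability = stab),
             "gammaDNF_hat", "toggle")
}

#' Generic pseudo-arclength continuation
#'
#' Continues the solution set of `f(x, p) = 0` in the scalar parameter `p`
#' over `window`, using a secant predictor and Newton corrector orthogonal
#' to the predictor direction, with step adaptation (halving on corrector
#' failure, growth on fast convergence).  Stability is classified from the
#' eigenvalues of the state Jacobian at each accepted point.
#'
#' @param f function `f(x, p)` returning a numeric vector of
#'   `length(x)` residuals.
#' @param x0 starting state (a fixed point at `p0`, refined internally).
#' @param p0 starting parameter value inside `window`.
#' @param window parameter interval to cover.
#' @param h0,hmax,hmin initial, maximal and minimal arclength steps.
#' @param max_points cap on the number of branch points.
#' @param direction +1 to start towards increasing `p`, -1 otherwise.
#' @return A `ghost_branch` data frame: `param`, one column per state
#'   component, `stability`.
#' @export
continue_branch <- function(f, x0, p0, window, h0 = 0.01, hmax = 0.1,
                            hmin = 1e-8, max_points = 2000,
                            direction = 1) {
  nx <- length(x0)
  newton <- function(z, resfun, tol = 1e-11) {
    for (it in 1:30) {
      r <- resfun(z)
      if (max(abs(r)) < tol) return(list(z = z, ok = TRUE, iters = it))
      J <- numeric_jacobian(resfun, z)
      dz <- tryCatch(solve(J, r), error = function(e) NULL)
      if (is.null(dz) || any(!is.finite(dz))) return(list(ok = FALSE))
      z <- z - dz
    }
    list(ok = FALSE)
  }
  # refine the seed to a fixed point at fixed p
  st <- newton(x0, function(x) f(x, p0))
  if (!st$ok) stop("continuation seed is not a fixed point")
  z <- c(st$z, p0)
  scale <- c(rep(1, nx), 1) # equal weighting of state and parameter
  stab_of <- function(z) {
    J <- numeric_jacobian(function(x) f(x, z[nx + 1]), z[1:nx])
    classify_stability(eigen(J)$values)
  }
  pts <- list(z)
  stabs <- stab_of(z)
  # first predictor: small parameter step
  z2 <- newton(z[1:nx], function(x) f(x, p0 + direction * h0))
  if (!z2$ok) stop("could not take the first continuation step")
  z2 <- c(z2$z, p0 + direction * h0)
  pts[[2]] <- z2
  stabs[2] <- stab_of(z2)
  h <- h0
  diag_msg <- NULL
  for (k in 3:max_points) {
    zp <- pts[[k - 1]]; zm <- pts[[k - 2]]
    tan <- (zp - zm) / sqrt(sum(((zp - zm) * scale)^2))
    pred <- zp + h * tan
    res <- function(z) c(f(z[1:nx], z[nx + 1]),
                         sum((z - pred) * tan * scale^2))
    sol <- newton(pred, res)
    while (!sol$ok && h > hmin) {
      h <- h / 2
      pred <- zp + h * tan
      sol <- newton(pred, res)
    }
    if (!sol$ok) {
      diag_msg <- sprintf("corrector failed near p = %.6g", zp[nx + 1])
      break
    }
    pts[[k]] <- sol$z
    stabs[k] <- stab_of(sol$z)
    if (sol$iters <= 3 && h < hmax) h <- min(hmax, 1.5 * h)
    p <- sol$z[nx + 1]
    if (p < min(window) - 1e-9 || p > max(window) + 1e-9) break
  }
  m <- do.call(rbind, pts)
  xn <- if (!is.null(names(x0))) names(x0) else paste0("x", seq_len(nx))
  df <- data.frame(param = m[, nx + 1], m[, seq_len(nx), drop = FALSE],
                   stability = stabs)
  names(df)[1 + seq_len(nx)] <- xn
  br <- new_branch(df, "p")
  attr(br, "diagnostic") <- diag_msg
  br
}

#' Saddle-node (fold) points of a steady-state branch
#'
#' Locates the turning points of a continuation branch and refines the
#' fold parameter values.  For closed-form toggle branches the fold is the
#' exact stationary point of the parametric branch `gamma(Ra)`; for generic
#' branches the three points around each turning index are interpolated by
#' a quadratic in the state and the fold refined by a bordered Newton solve
#' of the extended system `f = 0`, `J v = 0`, `|v| = 1` when `f` is
#' supplied.
#'
#' @param branch a `ghost_branch`.
#' @param params toggle parameters (closed-form branches only).
#' @param f the residual function used to build a generic branch.
#' @return Data frame of folds: `param`, state columns, `type`
#'   (`"SN1"`, `"SN2"`, ... by ascending parameter).
#' @export
locate_folds <- function(branch, params = NULL, f = NULL) {
  turning <- attr(branch, "turning")
  if (!length(turning)) return(NULL)
  out <- NULL
  if (identical(attr(branch, "model"), "toggle")) {
    stopifnot(!is.null(params))
    LRa <- branch$response[1] - branch$Ra[1]
    for (i in turning) {
      lo <- branch$Ra[max(1, i - 1)]; hi <- branch$Ra[min(nrow(branch), i + 1)]
      mx <- branch$param[i] > branch$param[max(1, i - 1)]
      o <- optimize(function(Ra) gamma_branch_value(Ra, params, LRa),
                    sort(c(lo, hi)), maximum = mx, tol = 1e-12)
      Ra <- if (mx) o$maximum else o$minimum
      out <- rbind(out, data.frame(param = gamma_branch_value(Ra, params,
                                                              LRa),
                                   Ra = Ra,
                                   Pa = toggle_Pa_stationary(params,
                                                             Ra + LRa)))
    }
  } else {
    state_cols <- setdiff(names(branch), c("param", "stability"))
    for (i in turning) {
      idx <- max(1, i - 1):min(nrow(branch), i + 1)
      x0 <- as.numeric(branch[i, state_cols])
      p0 <- branch$param[i]
      if (!is.null(f)) {
        fold <- refine_fold(f, x0, p0)
        row <- data.frame(param = fold$p, t(fold$x))
        names(row)[-1] <- state_cols
      } else {
        # quadratic vertex through the three bracketing points
        s <- seq_along(idx)
        fit <- lm(branch$param[idx] ~ s + I(s^2))
        b <- coef(fit)
        sv <- -b[2] / (2 * b[3])
        row <- data.frame(param = b[1] + b[2] * sv + b[3] * sv^2,
                          t(vapply(state_cols, function(cn)
                            approx(s, branch[[cn]][idx], sv)$y, 1)))
        names(row)[-1] <- state_cols
      }
      out <- rbind(out, row)
    }
  }
  out <- out[order(out$param), , drop = FALSE]
  out$type <- paste0("SN", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

# Newton solve of the bordered fold system: f(x,p) = 0, J(x,p) v = 0,
# c'v = 1, unknowns (x, p, v).
refine_fold <- function(f, x0, p0, tol = 1e-11) {
  nx <- length(x0)
  J0 <- numeric_jacobian(function(x) f(x, p0), x0)
  sv <- svd(J0)
  v0 <- sv$v[, nx]
  cvec <- v0
  z <- c(x0, p0, v0)
  resfun <- function(z) {
    x <- z[1:nx]; p <- z[nx + 1]; v <- z[nx + 1 + 1:nx]
    J <- numeric_jacobian(function(xx) f(xx, p), x)
    c(f(x, p), J %*% v, sum(cvec * v) - 1)
  }
  for (it in 1:40) {
    r <- resfun(z)
    if (max(abs(r)) < tol) break
    J <- numeric_jacobian(resfun, z)
    dz <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(dz)) stop("fold refinement failed (singular system)")
    z <- z - dz
  }
  list(x = z[1:nx], p = z[nx + 1], v = z[nx + 1 + 1:nx],
       residual = max(abs(resfun(z))))
}

#' Fold locations of the toggle switch (exact)
#'
#' Stationary points of the closed-form branch `gamma(Ra)` at constant
#' input: the two saddle-node bifurcations bounding the bistable region.
#' With the published parameters and zero input the folds sit at
#' `gammaDNF_hat` of about 0.83 (SN1) and 2.95 (SN2).
#'
#' @param params [toggle_params()].
#' @param LRa constant input.
#' @return Data frame `param`, `Ra`, `Pa`, `type`; `NULL` when no fold
#'   exists (monostable for every `gammaDNF_hat`).
#' @export
toggle_folds <- function(params, LRa = 0) {
  g <- function(Ra) gamma_branch_value(Ra, params, LRa)
  # gamma(Ra) diverges at Ra -> 0 and vanishes at Ra -> 1; a fold pair is
  # an interior local minimum (SN1) followed by a local maximum (SN2)
  xs <- exp(seq(log(1e-5), log(1 - LRa - 1e-6), length.out = 2000))
  v <- g(xs)
  locmax <- which(diff(sign(diff(v))) == -2) + 1
  locmin <- which(diff(sign(diff(v))) == 2) + 1
  if (!length(locmax) || !length(locmin)) return(NULL)
  refine <- function(i, mx) {
    o <- optimize(g, c(xs[i - 1], xs[i + 1]), maximum = mx, tol = 1e-12)
    if (mx) c(o$maximum, o$objective) else c(o$minimum, o$objective)
  }
  up <- refine(locmax[1], TRUE)
  lo <- refine(locmin[1], FALSE)
  out <- data.frame(param = c(lo[2], up[2]), Ra = c(lo[1], up[1]))
  out$Pa <- toggle_Pa_stationary(params, out$Ra + LRa)
  out$type <- c("SN1", "SN2")
  out
}

#' Fold curve of the toggle in the (input, reactivity) plane
#'
#' Tracks both saddle-node branches as functions of the constant input
#' `LRa`; the bistable region closes at a cusp where the two folds merge.
#'
#' @param params [toggle_params()].
#' @param LRa_max upper end of the input scan.
#' @param n number of input values.
#' @return List with `curve` (data frame `LRa`, `param`, `Ra`, `type`) and
#'   `cusp` (input and reactivity at the cusp).
#' @export
toggle_fold_curve <- function(params, LRa_max = 0.2, n = 81) {
  has_fold <- function(LRa) !is.null(toggle_folds(params, LRa))
  lra <- seq(0, LRa_max, length.out = n)
  curve <- NULL
  for (v in lra) {
    fl <- toggle_folds(params, v)
    if (!is.null(fl))
      curve <- rbind(curve, data.frame(LRa = v, fl))
  }
  # cusp: largest input still admitting a fold pair
  lo <- max(curve$LRa); hi <- LRa_max
  if (!has_fold(hi)) {
    for (i in 1:50) {
      mid <- (lo + hi) / 2
      if (has_fold(mid)) lo <- mid else hi <- mid
    }
  }
  fl <- toggle_folds(params, lo)
  cusp <- c(LRa = lo, param = mean(fl$param))
  list(curve = curve, cusp = cusp)
}

#' Fold of the compartment model in total receptor concentration
#'
#' Position of the saddle-node SN2 in `RT` at zero ligand: along the exact
#' branch parameterized by the membrane active fraction `RaPM` (solving the
#' remaining steady-state relations and the conservation constraint for
#' `RT`), the fold is the minimum of `RT(RaPM)` over the upper branch.
#' At the published parameters this is the critical organization
#' `RT ~ 1.35`.
#'
#' @param params [compartment_params()].
#' @param RaPM_range interval of membrane active fractions bracketing the
#'   fold (the basal branch at very small `RaPM` is excluded).
#' @param RT_range search interval for `RT`.
#' @return List `RT`, `RaPM`, `state` (full 7-component fold state).
#' @export
compartment_fold_rt <- function(params, RaPM_range = c(0.02, 0.9),
                                RT_range = c(0.2, 8)) {
  rt_of <- function(RaPM) {
    g <- function(RT) {
      pp <- params; pp$RT <- RT
      compartment_conservation_residual(RaPM, pp)
    }
    lo <- RT_range[1]; hi <- RT_range[2]
    glo <- g(lo); ghi <- g(hi)
    if (is.na(glo) || is.na(ghi) || glo * ghi > 0) return(NA_real_)
    uniroot(g, c(lo, hi), tol = 1e-13)$root
  }
  o <- optimize(function(s) {
    v <- rt_of(s); if (is.na(v)) 1e6 else v
  }, RaPM_range, tol = 1e-11)
  if (o$objective >= 1e6) stop("no fold found in the given RaPM range")
  pp <- params; pp$RT <- o$objective
  list(RT = o$objective, RaPM = o$minimum,
       state = compartment_state_from_RaPM(o$minimum, pp))
}

#' Two-parameter fold curve of the compartment model
#'
#' Tracks the saddle-node SN2 in the (recycling rate, total receptor)
#' plane at zero ligand: for each `krec` the one-parameter fold in `RT` is
#' recomputed, giving the curve `RT_fold(krec)`.  The curve decreases with
#' `krec` and approaches a positive asymptote (see
#' [compartment_rt_asymptote()]).
#'
#' @param params [compartment_params()].
#' @param krec_values recycling rates to scan.
#' @return Data frame `krec`, `RT`, `RaPM`.
#' @export
compartment_fold_curve <- function(params,
                                   krec_values = 0.042 * 2^(0:8)) {
  out <- lapply(krec_values, function(kr) {
    pp <- params; pp$krec <- kr
    f <- compartment_fold_rt(pp)
    data.frame(krec = kr, RT = f$RT, RaPM = f$RaPM)
  })
  do.call(rbind, out)
}

#' Large-krec asymptote of the compartment fold
#'
#' Evaluates the fold `RT` at 100x and 200x the default recycling rate and
#' reports the Richardson-extrapolated (in 1/krec) large-`krec` limit,
#' flagging convergence when the two evaluations differ by less than 0.1%.
#'
#' @param params [compartment_params()].
#' @param factors the two recycling-rate multipliers.
#' @return List `RT_asymp`, `values` (the two fold positions),
#'   `converged`.
#' @export
compartment_rt_asymptote <- function(params, factors = c(100, 200)) {
  vals <- vapply(factors, function(f) {
    pp <- params; pp$krec <- params$krec * f
    compartment_fold_rt(pp)$RT
  }, 1)
  # RT(k) ~ RT_inf + c/k: eliminate the 1/k term
  k <- params$krec * factors
  rt_inf <- (vals[2] * k[2] - vals[1] * k[1]) / (k[2] - k[1])
  list(RT_asymp = rt_inf, values = setNames(vals, paste0(factors, "x")),
       converged = abs(diff(vals)) / abs(vals[1]) < 1e-3)
}

#' Steady-state dose-response with hysteresis annotation
#'
#' Stable steady-state responses `Ra + LRa` for each constant input dose,
#' with the switch-on dose (where the basal branch disappears) and
#' switch-off dose (where the high branch disappears) for hysteretic
#' organizations.  In the irreversibly bistable regime the high branch
#' persists down to zero input and no switch-off dose exists.
#'
#' @param params [toggle_params()].
#' @param doses input grid in `[0, 1)`.
#' @return List with `responses` (data frame `dose`, `response`, `branch`),
#'   `switch_on`, `switch_off` (NA when not applicable) and `regime`.
#' @export
dose_response <- function(params, doses = seq(0, 0.2, by = 0.002)) {
  stopifnot(all(doses >= 0), all(doses < 1))
  n_stable <- function(d)
    sum(toggle_fixed_points(params, d)$stability == "stable")
  rows <- lapply(doses, function(d) {
    fp <- toggle_fixed_points(params, d)
    fp <- fp[fp$stability == "stable", ]
    if (!nrow(fp)) return(NULL)
    branch <- if (nrow(fp) == 1) "single"
              else c("low", rep("high", nrow(fp) - 1))
    data.frame(dose = d, response = fp$response, branch = branch)
  })
  responses <- do.call(rbind, rows)
  bist <- vapply(doses, n_stable, 1) > 1
  refine <- function(lo, hi, want_bistable_low) {
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if ((n_stable(mid) > 1) == want_bistable_low) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  switch_on <- switch_off <- NA_real_
  if (any(bist)) {
    i_hi <- max(which(bist))
    if (i_hi < length(doses))
      switch_on <- refine(doses[i_hi], doses[i_hi + 1], TRUE)
    i_lo <- min(which(bist))
    if (i_lo > 1)
      switch_off <- refine(doses[i_lo - 1], doses[i_lo], FALSE)
  }
  regime <- if (!any(bist)) "monostable"
            else if (is.na(switch_off)) "irreversible"
            else "hysteretic"
  list(responses = responses, switch_on = switch_on,
       switch_off = switch_off, regime = regime)
}

#' Dynamic range of receptor activation across organizations
#'
#' For each specific-reactivity value, the reversible activation
#' amplitude: the steady response reached from the basal state under the
#' activating input (the ligand level producing 15% bound receptors)
#' minus the resting response the system relaxes to after the input is
#' removed again.  In the monostable regime the activated response itself
#' shrinks; in the irreversibly bistable regime the system stays high
#' after input removal, collapsing the range -- so the gain peaks at the
#' saddle-node organization.
#'
#' @param params [toggle_params()] (its `gammaDNF_hat` is overridden).
#' @param gammas grid of `gammaDNF_hat` values.
#' @param input target ligand-bound occupancy of the activating input.
#' @param settle_min settling horizon (minutes) per phase.
#' @return Data frame `gamma`, `resting`, `activated`, `gain`.
#' @export
dynamic_range_scan <- function(params, gammas = seq(2.3, 5, by = 0.025),
                               input = 0.15, settle_min = 600) {
  rows <- lapply(gammas, function(g) {
    pp <- params; pp$gammaDNF_hat <- g
    basal <- toggle_basal_state(pp)
    if (input == 0) {
      act <- rest <- basal[["Ra"]]
    } else {
      LT <- ligand_for_target_occupancy(pp, input)
      prot <- new_pulse_train(0, settle_min, LT, 2 * settle_min)
      tr <- simulate_model("toggle", pp, prot, init = basal,
                           horizon = 2 * settle_min,
                           dt_out = settle_min / 25)
      r <- response(tr)
      act <- r[which.min(abs(tr$times_min - settle_min))]
      rest <- r[length(r)]
    }
    data.frame(gamma = g, resting = rest, activated = act,
               gain = act - rest)
  })
  do.call(rbind, rows)
}
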