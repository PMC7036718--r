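# Core dynamical models: right-hand sides, fixed points, deterministic
# simulation.  The R-level derivative functions are independent
# reimplementations of the compiled right-hand sides and are cross-checked
# against them in the test suite.

check_state <- function(x, lo = 0, hi = 1, tol = 1e-6, what = "state") {
  if (any(!is.finite(x)) || any(x < lo - tol) || any(x > hi + tol))
    stop(what, " outside [", lo, ", ", hi, "] beyond tolerance: ",
         paste(signif(x, 6), collapse = ", "))
  invisible(x)
}

#' Toggle-switch time derivatives
#'
#' Right-hand side of the two-component receptor/phosphatase switch.  With
#' `ligand_dynamic = TRUE` the ligand-bound fraction `LRa` is a state
#' variable (`Ri = 1 - Ra - LRa`) driven by binding of the total ligand
#' `params$LT`; otherwise `LRa` is an external constant (`Ri = 1 - Ra`) and
#' its derivative is zero.  The time-scale constants `kR`, `k1` multiply
#' the full bracketed rate expressions and hence do not move steady states.
#'
#' @param state named numeric with `Ra`, `Pa` and (optionally) `LRa`.
#' @param params [toggle_params()].
#' @param ligand_dynamic logical, see above.
#' @return Named vector `(dRa, dPa, dLRa)`.
#' @examples
#' p <- toggle_params(gammaDNF_hat = 2.957)
#' toggle_derivatives(c(Ra = 0, Pa = 1 / 1.5, LRa = 0), p)
#' @export
toggle_derivatives <- function(state, params, ligand_dynamic = TRUE) {
  Ra <- state[["Ra"]]; Pa <- state[["Pa"]]
  LRa <- if ("LRa" %in% names(state)) state[["LRa"]] else 0
  check_state(c(Ra, Pa, LRa))
  with(params, {
    if (ligand_dynamic) {
      Ri <- 1 - Ra - LRa
      dRa <- kR * (Ri * (alpha1 * Ri + alpha2 * Ra + alpha3 * LRa) -
                     gammaDNF_hat * Pa * Ra) - kon * Ra * LT +
        0.5 * koff * LRa
      dLRa <- kon * (Ra + Ri) * LT - koff * LRa
    } else {
      Ri <- 1 - Ra
      dRa <- kR * (Ri * (alpha1 * Ri + alpha2 * Ra + alpha3 * LRa) -
                     gammaDNF_hat * Pa * Ra)
      dLRa <- 0
    }
    dPa <- k1 * ((1 - Pa) - k21 * Pa - betaDNF_hat * Pa * (Ra + LRa))
    c(dRa = dRa, dPa = dPa, dLRa = dLRa)
  })
}

#' Dynamic recycling rate of the self-organization law
#'
#' Recycling rate `krec` scaled by the multiplier
#' `(RT - RT_asymp) / (RT (1 - LRiE) - RT_asymp)`, which grows as receptors
#' are degraded (`LRiE` increases) so that the membrane receptor
#' concentration is held near the saddle-node.  The multiplier is capped at
#' `params$sat` (2.5); a non-positive denominator falls to the cap.
#'
#' @param LRiE accumulated degraded (endosomal ligand-bound) fraction,
#'   in `[0, 1)`.
#' @param params [compartment_params()].
#' @return The effective recycling rate.
#' @export
dynamic_recycling_rate <- function(LRiE, params) {
  stopifnot(all(LRiE >= 0), all(LRiE < 1))
  den <- params$RT * (1 - LRiE) - params$RT_asymp
  m <- ifelse(den <= 0, params$sat,
              pmin((params$RT - params$RT_asymp) / den, params$sat))
  params$krec * m
}

#' Compartment-model time derivatives
#'
#' Right-hand side of the seven-species plasma-membrane/endosome receptor
#' trafficking model.  Degradation moves mass into the accumulator `LRiE`,
#' so the seven derivatives sum to zero exactly.
#'
#' @param state named numeric with `RaPM`, `RiPM`, `Pa`, `LRaPM`, `RaE`,
#'   `RiE`, `LRiE`.
#' @param params [compartment_params()].
#' @param dynamic_krec if `TRUE` the recycling rate follows
#'   [dynamic_recycling_rate()].
#' @return Named vector of the seven derivatives.
#' @export
compartment_derivatives <- function(state, params, dynamic_krec = FALSE) {
  s <- state[c("RaPM", "RiPM", "Pa", "LRaPM", "RaE", "RiE", "LRiE")]
  check_state(unname(s))
  with(params, {
    RaPM <- s[["RaPM"]]; RiPM <- s[["RiPM"]]; Pa <- s[["Pa"]]
    LRaPM <- s[["LRaPM"]]; RaE <- s[["RaE"]]; RiE <- s[["RiE"]]
    LRiE <- s[["LRiE"]]
    kr <- if (dynamic_krec) dynamic_recycling_rate(LRiE, params) else krec
    act <- RT * RiPM * (alpha1 * RiPM + alpha2 * RaPM + alpha3 * LRaPM)
    dephos <- gammaDNF * PDNFT * Pa * RaPM + gammaNR * PNRT * RaPM
    c(RaPM = act - dephos - kin * RaPM - kon * RaPM * LT +
        0.5 * koff * LRaPM,
      RiPM = -act + dephos - kini * kin * RiPM + kr * RiE -
        kon * RiPM * LT + 0.5 * koff * LRaPM,
      Pa = k1 * ((1 - Pa) - k21 * Pa - betaDNF * Pa * RT * (RaPM + LRaPM)),
      LRaPM = kon * (RaPM + RiPM) * LT - koff * LRaPM -
        kdeg * kin * LRaPM,
      RaE = kin * RaPM - gammaNF * PNFT * RaE,
      RiE = kini * kin * RiPM + gammaNF * PNFT * RaE - kr * RiE,
      LRiE = kdeg * kin * LRaPM)
  })
}

# Stationary phosphatase fraction given the total active receptor level.
toggle_Pa_stationary <- function(params, RaL) {
  1 / (1 + params$k21 + params$betaDNF_hat * RaL)
}

# Closed-form steady-state branch of the toggle at constant input:
# gammaDNF_hat as a function of Ra (substituting the stationary Pa).
gamma_branch_value <- function(Ra, params, LRa = 0) {
  with(params, (1 - Ra) * (alpha1 * (1 - Ra) + alpha2 * Ra + alpha3 * LRa) *
         (1 + k21 + betaDNF_hat * (Ra + LRa)) / Ra)
}

# Numeric Jacobian by central differences.
numeric_jacobian <- function(f, x, eps = 1e-7) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (i in seq_len(n)) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

classify_stability <- function(eig) {
  re <- Re(eig)
  if (all(re < 0)) "stable"
  else if (any(re < 0) && any(re > 0) && all(abs(Im(eig)) < 1e-12)) "saddle"
  else "unstable"
}

#' Fixed points of the toggle switch at constant input
#'
#' All real fixed points in the unit square for the given constant
#' ligand-bound fraction, with linear-stability classification from the
#' eigenvalues of the Jacobian, sorted by `Ra`.
#'
#' @param params [toggle_params()].
#' @param LRa constant ligand-bound input fraction, in `[0, 1)`.
#' @param n_scan grid resolution of the root bracketing scan.
#' @return Data frame with columns `Ra`, `Pa`, `response` (`Ra + LRa`) and
#'   `stability` (`"stable"`, `"saddle"`, `"unstable"`).
#' @export
toggle_fixed_points <- function(params, LRa = 0, n_scan = 4000) {
  stopifnot(LRa >= 0, LRa < 1)
  f1 <- function(Ra) { # dRa/dt at the stationary Pa, up to the factor kR
    Pa <- toggle_Pa_stationary(params, Ra + LRa)
    Ri <- 1 - Ra
    Ri * (params$alpha1 * Ri + params$alpha2 * Ra + params$alpha3 * LRa) -
      params$gammaDNF_hat * Pa * Ra
  }
  grid <- seq(0, 1, length.out = n_scan)
  v <- vapply(grid, f1, 1)
  roots <- grid[v == 0]
  for (i in seq_len(n_scan - 1)) {
    if (v[i] * v[i + 1] < 0)
      roots <- c(roots, uniroot(f1, grid[i + 0:1], tol = 1e-14)$root)
  }
  roots <- sort(unique(roots))
  if (!length(roots))
    return(data.frame(Ra = numeric(0), Pa = numeric(0),
                      response = numeric(0), stability = character(0)))
  out <- lapply(roots, function(Ra) {
    Pa <- toggle_Pa_stationary(params, Ra + LRa)
    J <- numeric_jacobian(function(y) {
      toggle_derivatives(c(Ra = y[1], Pa = y[2], LRa = LRa), params,
                         ligand_dynamic = FALSE)[1:2]
    }, c(Ra, Pa))
    data.frame(Ra = Ra, Pa = Pa, response = Ra + LRa,
               stability = classify_stability(eigen(J)$values))
  })
  do.call(rbind, out)
}

# Basal fixed point of the toggle (lowest-Ra stable state at LRa = 0).
toggle_basal_state <- function(params) {
  fp <- toggle_fixed_points(params, LRa = 0)
  fp <- fp[fp$stability == "stable", ]
  c(Ra = fp$Ra[1], Pa = fp$Pa[1], LRa = 0)
}

#' Fixed points of the compartment model at zero ligand
#'
#' Steady states of the trafficking model for `LT = 0` (ligand-bound
#' species identically zero, degradation inactive).  Uses the conservation
#' constraint to reduce to a one-dimensional root scan in `RaPM`; stability
#' is classified on the reduced four-dimensional system
#' (`RaPM`, `Pa`, `RaE`, `RiE`) with `RiPM` eliminated.
#'
#' @param params [compartment_params()].
#' @param n_scan grid resolution of the root bracketing scan.
#' @return Data frame with the seven state components plus `stability`.
#' @export
compartment_fixed_points <- function(params, n_scan = 4000) {
  resid <- function(RaPM) compartment_conservation_residual(RaPM, params)
  grid <- seq(1e-8, 1 - 1e-8, length.out = n_scan)
  v <- vapply(grid, resid, 1)
  roots <- c()
  for (i in seq_len(n_scan - 1)) {
    if (!is.na(v[i]) && !is.na(v[i + 1]) && v[i] * v[i + 1] < 0)
      roots <- c(roots, uniroot(resid, grid[i + 0:1], tol = 1e-14)$root)
  }
  out <- lapply(roots, function(RaPM) {
    st <- compartment_state_from_RaPM(RaPM, params)
    J <- numeric_jacobian(function(y) compartment_reduced_rhs(y, params),
                          st[c("RaPM", "Pa", "RaE", "RiE")])
    data.frame(t(st), stability = classify_stability(eigen(J)$values))
  })
  do.call(rbind, out)
}

# Given RaPM (and zero ligand), solve the remaining steady-state relations
# in closed form; returns the full 7-component state (not necessarily
# satisfying conservation -- see compartment_conservation_residual).
compartment_state_from_RaPM <- function(RaPM, params) {
  with(params, {
    Pa <- 1 / (1 + k21 + betaDNF * RT * RaPM)
    # dRaPM = 0: RT RiPM (a1 RiPM + a2 RaPM) = (gDNF PDNFT Pa + gNR PNRT
    # + kin) RaPM, a quadratic in RiPM (positive root)
    loss <- (gammaDNF * PDNFT * Pa + gammaNR * PNRT + kin) * RaPM
    A <- RT * alpha1; B <- RT * alpha2 * RaPM
    RiPM <- if (A > 0) (-B + sqrt(B^2 + 4 * A * loss)) / (2 * A)
            else if (B > 0) loss / B else 0
    RaE <- kin * RaPM / (gammaNF * PNFT)
    RiE <- (kini * kin * RiPM + gammaNF * PNFT * RaE) / krec
    c(RaPM = RaPM, RiPM = RiPM, Pa = Pa, LRaPM = 0, RaE = RaE, RiE = RiE,
      LRiE = 0)
  })
}

compartment_conservation_residual <- function(RaPM, params) {
  st <- compartment_state_from_RaPM(RaPM, params)
  st[["RaPM"]] + st[["RiPM"]] + st[["RaE"]] + st[["RiE"]] - 1
}

# Reduced zero-ligand compartment dynamics used for continuation and
# stability: y = (RaPM, Pa, RaE, RiE), RiPM = 1 - RaPM - RaE - RiE.
compartment_reduced_rhs <- function(y, params) {
  st <- c(RaPM = y[[1]], RiPM = 1 - y[[1]] - y[[3]] - y[[4]], Pa = y[[2]],
          LRaPM = 0, RaE = y[[3]], RiE = y[[4]], LRiE = 0)
  d <- compartment_derivatives_unsafe(st, params)
  unname(d[c("RaPM", "Pa", "RaE", "RiE")])
}

# As compartment_derivatives() but without the admissibility guard, for use
# inside Newton iterations that may step slightly outside [0, 1].
compartment_derivatives_unsafe <- function(state, params,
                                           dynamic_krec = FALSE) {
  with(params, {
    RaPM <- state[["RaPM"]]; RiPM <- state[["RiPM"]]; Pa <- state[["Pa"]]
    LRaPM <- state[["LRaPM"]]; RaE <- state[["RaE"]]; RiE <- state[["RiE"]]
    LRiE <- state[["LRiE"]]
    kr <- if (dynamic_krec) dynamic_recycling_rate(LRiE, params) else krec
    act <- RT * RiPM * (alpha1 * RiPM + alpha2 * RaPM + alpha3 * LRaPM)
    dephos <- gammaDNF * PDNFT * Pa * RaPM + gammaNR * PNRT * RaPM
    c(RaPM = act - dephos - kin * RaPM - kon * RaPM * LT +
        0.5 * koff * LRaPM,
      RiPM = -act + dephos - kini * kin * RiPM + kr * RiE -
        kon * RiPM * LT + 0.5 * koff * LRaPM,
      Pa = k1 * ((1 - Pa) - k21 * Pa - betaDNF * Pa * RT * (RaPM + LRaPM)),
      LRaPM = kon * (RaPM + RiPM) * LT - koff * LRaPM -
        kdeg * kin * LRaPM,
      RaE = kin * RaPM - gammaNF * PNFT * RaE,
      RiE = kini * kin * RiPM + gammaNF * PNFT * RaE - kr * RiE,
      LRiE = kdeg * kin * LRaPM)
  })
}

model_id <- function(model) {
  switch(model, toggle = 0L, toggle_input = 1L, compartment = 2L,
         decay = 3L, gradient = 4L,
         stop("unknown model: ", model))
}

model_state_names <- function(model) {
  switch(model,
         toggle = c("Ra", "Pa", "LRa"),
         toggle_input = c("Ra", "Pa"),
         compartment = c("RaPM", "RiPM", "Pa", "LRaPM", "RaE", "RiE",
                         "LRiE"),
         decay = "Ra",
         gradient = c("x", "y"))
}

default_init <- function(model, params) {
  switch(model,
         toggle = toggle_basal_state(params),
         toggle_input = toggle_basal_state(params)[c("Ra", "Pa")],
         compartment = {
           fp <- compartment_fixed_points(params)
           fp <- fp[fp$stability == "stable", ]
           unlist(fp[which.min(fp$RaPM),
                     c("RaPM", "RiPM", "Pa", "LRaPM", "RaE", "RiE",
                       "LRiE")])
         },
         decay = c(Ra = 0),
         stop("no default initial state for model ", model))
}

new_trajectory <- function(model, times_units, states, input, protocol,
                           params, seed = NA_integer_) {
  colnames(states) <- model_state_names(model)[seq_len(ncol(states))]
  structure(list(model = model, times = times_units,
                 times_min = times_units / units_per_minute(),
                 states = states, input = input, protocol = protocol,
                 params = params, seed = seed),
            class = "ghost_trajectory")
}

#' Receptor activity response of a trajectory
#'
#' The reported response is the total active receptor fraction:
#' `Ra + LRa` for the toggle switch (in parameter mode `LRa` is the driven
#' input), `RaPM + LRaPM` for the compartment model and `Ra` for the decay
#' model.
#'
#' @param traj a trajectory from [simulate_model()] or [decay_simulate()].
#' @return Numeric vector of the response at the trajectory sample times.
#' @export
response <- function(traj) {
  s <- traj$states
  switch(traj$model,
         toggle = s[, "Ra"] + s[, "LRa"],
         toggle_input = s[, "Ra"] + traj$input,
         compartment = s[, "RaPM"] + s[, "LRaPM"],
         decay = s[, "Ra"],
         stop("no response defined for model ", traj$model))
}

#' Deterministic model simulation
#'
#' Integrates one of the deterministic models with an adaptive
#' Dormand-Prince scheme (relative tolerance 1e-8, absolute 1e-10 by
#' default) under a piecewise-constant stimulation protocol.
#'
#' Models: `"toggle"` (dynamic ligand; the protocol amplitude is the total
#' ligand `LT`), `"toggle_input"` (the ligand-bound fraction `LRa` is
#' driven directly as a step input), `"compartment"` (protocol amplitude is
#' `LT`), `"decay"` (protocol is the 0/1 pulse indicator `I`).
#'
#' @param model model name, see Details.
#' @param params matching parameter object.
#' @param protocol a `pulse_train`; `NULL` means no input over `horizon`.
#' @param init named initial state; `NULL` starts from the basal fixed
#'   point (zero for the decay model).
#' @param horizon horizon in minutes (defaults to the protocol's).
#' @param dt_out output sampling interval in minutes.
#' @param rtol,atol integrator tolerances.
#' @param dynamic_krec compartment model only: use the dynamic recycling
#'   law.
#' @param amplitude overrides the protocol amplitude; for ligand-driven
#'   models the default is the calibrated level giving 15% steady-state
#'   occupancy; for `"toggle_input"` it is 0.15; for `"decay"` it is 1.
#' @return A `ghost_trajectory` with sampled states, input and response.
#' @examples
#' p <- toggle_params(gammaDNF_hat = organization_gamma("critical"))
#' tr <- simulate_model("toggle", p, step_protocol(5, 10), horizon = 60)
#' max(response(tr))
#' @export
simulate_model <- function(model = c("toggle", "toggle_input",
                                     "compartment", "decay"),
                           params, protocol = NULL, init = NULL,
                           horizon = NULL, dt_out = 0.1, rtol = 1e-8,
                           atol = 1e-10, dynamic_krec = FALSE,
                           amplitude = NULL) {
  model <- match.arg(model)
  if (is.null(protocol)) {
    if (is.null(horizon)) stop("need a protocol or an explicit horizon")
    protocol <- new_pulse_train(numeric(0), 0, 0, horizon)
  }
  if (is.null(amplitude)) amplitude <- protocol$amplitude
  if (is.null(amplitude))
    amplitude <- switch(model,
                        toggle = ,
                        compartment = ligand_for_target_occupancy(params),
                        toggle_input = 0.15,
                        decay = 1)
  if (is.null(horizon)) horizon <- protocol$horizon
  if (horizon > protocol$horizon)
    protocol$horizon <- horizon
  seg <- protocol_segments(protocol, amplitude, horizon)
  if (is.null(init)) init <- default_init(model, params)
  pv <- if (model == "compartment")
    as_param_vector(params, dynamic_krec = dynamic_krec)
  else as_param_vector(params)
  upm <- units_per_minute()
  out_times <- seq(0, horizon, by = dt_out) * upm
  states <- .ode_drive_cpp(model_id(model), pv, unname(init), seg$breaks,
                           seg$values, out_times, rtol, atol, 0L)
  u <- numeric(length(out_times))
  idx <- findInterval(out_times, seg$breaks, left.open = TRUE) + 1
  u <- seg$values[pmin(idx, length(seg$values))]
  new_trajectory(model, out_times, states, u, protocol, params)
}

#' Exponential-decay baseline simulation
#'
#' Solves `dRa/dt = I alpha (RT - Ra) - beta Ra` with the 0/1 pulse
#' indicator `I` following the protocol.
#'
#' @inheritParams simulate_model
#' @param params [decay_params()].
#' @return A `ghost_trajectory`.
#' @export
decay_simulate <- function(params, protocol = NULL, init = NULL,
                           horizon = NULL, dt_out = 0.1, rtol = 1e-8,
                           atol = 1e-10) {
  simulate_model("decay", params, protocol, init = init, horizon = horizon,
                 dt_out = dt_out, rtol = rtol, atol = atol, amplitude = 1)
}

#' @export
print.ghost_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory of model '%s': %d samples over %.1f min\n",
              x$model, length(x$times), max(x$times_min)))
  invisible(x)
}

#' @export
as.data.frame.ghost_trajectory <- function(x, ...) {
  data.frame(time_min = x$times_min, x$states, input = x$input,
             response = response(x))
}
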