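# Response metrics: activity thresholding, disjoint-interval counting,
# total active duration, and ensembles over random pulse trains.

#' Organization-adaptive activity threshold
#'
#' The activity threshold used for interval detection: the midpoint
#' between the basal steady response at zero input and the activated
#' steady response reached from the basal state under the standard
#' activating input (`LRa = 0.15`).
#'
#' @param params [toggle_params()] or [decay_params()].
#' @param input target ligand-bound occupancy of the activating input.
#' @param frac position between basal and activated response (0.5 =
#'   midpoint).
#' @param settle_min settling horizon in minutes.
#' @return The threshold on the response scale.
#' @export
activity_threshold <- function(params, input = 0.15, frac = 0.5,
                               settle_min = 600) {
  if (inherits(params, "decay_params")) {
    act <- params$alpha * params$RT / (params$alpha + params$beta)
    return(frac * act)
  }
  basal <- toggle_basal_state(params)
  prot <- new_pulse_train(0, settle_min, input, settle_min)
  tr <- simulate_model("toggle_input", params, prot,
                       init = basal[c("Ra", "Pa")], horizon = settle_min,
                       dt_out = settle_min / 50, amplitude = input)
  act <- tr$states[nrow(tr$states), "Ra"] + input
  basal[["Ra"]] + frac * (act - basal[["Ra"]])
}

# Activated steady response in dynamic-ligand mode (ligand calibrated to
# the target occupancy); this is the pulse-response amplitude the decay
# presets are calibrated against.
toggle_activated_amplitude <- function(params, input = 0.15,
                                       settle_min = 600) {
  basal <- toggle_basal_state(params)
  LT <- ligand_for_target_occupancy(params, input)
  prot <- new_pulse_train(0, settle_min, LT, settle_min)
  tr <- simulate_model("toggle", params, prot, init = basal,
                       horizon = settle_min, dt_out = settle_min / 50)
  response(tr)[length(tr$times)]
}

#' Disjoint intervals of receptor activity
#'
#' Maximal runs of the trajectory response at or above the threshold, with
#' crossing times refined by linear interpolation between output samples.
#'
#' @param traj a `ghost_trajectory`.
#' @param threshold activity threshold in `(0, 1)`.
#' @return An `interval_set`: data frame of half-open `[start, end)`
#'   intervals in minutes, with attributes `threshold` and `horizon_min`.
#' @export
activity_intervals <- function(traj, threshold) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  t <- traj$times_min
  r <- response(traj)
  on <- r >= threshold
  out <- NULL
  cross <- function(i) { # upward/downward crossing between samples i, i+1
    t[i] + (threshold - r[i]) / (r[i + 1] - r[i]) * (t[i + 1] - t[i])
  }
  i <- 1
  n <- length(t)
  while (i <= n) {
    if (on[i]) {
      start <- if (i == 1) t[1] else cross(i - 1)
      j <- i
      while (j < n && on[j + 1]) j <- j + 1
      end <- if (j == n) t[n] else cross(j)
      out <- rbind(out, c(start, end))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(out))
    out <- matrix(numeric(0), 0, 2)
  df <- data.frame(start = out[, 1], end = out[, 2])
  structure(df, class = c("interval_set", "data.frame"),
            threshold = threshold, horizon_min = max(t))
}

#' Total active duration as a fraction of the horizon
#'
#' @param intervals an `interval_set` from [activity_intervals()].
#' @param horizon horizon in minutes (defaults to the interval set's).
#' @return Total interval duration divided by the horizon, in `[0, 1]`.
#' @export
total_active_fraction <- function(intervals, horizon = NULL) {
  if (is.null(horizon)) horizon <- attr(intervals, "horizon_min")
  if (!nrow(intervals)) return(0)
  sum(intervals$end - intervals$start) / horizon
}

#' Pulse-train response ensemble
#'
#' Simulates the toggle switch (dynamic ligand) under `n_trains`
#' independent random pulse trains and extracts, per realization, the
#' total active fraction and the number of disjoint activity intervals.
#' The published ensembles use 1,000 trains of twelve 5-min pulses over
#' 480 min per organization.
#'
#' @param params [toggle_params()]; use [organization_gamma()] for the
#'   canonical organizations.
#' @param n_trains ensemble size.
#' @param seed master seed; per-train seeds are derived deterministically.
#' @param n_pulses,pulse_len,horizon train geometry (minutes).
#' @param dt_out response sampling interval (minutes).
#' @param threshold activity threshold; `NULL` = [activity_threshold()].
#' @param simulate_fun function `(train, threshold)` returning a
#'   per-realization record; the default runs the toggle switch.  Used by
#'   [decay_tradeoff_suite()] to substitute the decay model.
#' @return Data frame `train_seed`, `fraction`, `n_intervals` with
#'   attributes `threshold`, `params`, `failed` (count of excluded
#'   failures).
#' @export
ensemble_run <- function(params, n_trains = 1000, seed = 1,
                         n_pulses = 12, pulse_len = 5, horizon = 480,
                         dt_out = 0.1, threshold = NULL,
                         simulate_fun = NULL) {
  stopifnot(n_trains >= 1)
  if (is.null(threshold)) threshold <- activity_threshold(params)
  amp <- if (inherits(params, "toggle_params"))
    ligand_for_target_occupancy(params) else 1
  init <- if (inherits(params, "toggle_params"))
    toggle_basal_state(params) else NULL
  if (is.null(simulate_fun)) {
    simulate_fun <- function(train, threshold) {
      tr <- simulate_model(
        if (inherits(params, "decay_params")) "decay" else "toggle",
        params, train, init = init, dt_out = dt_out, amplitude = amp)
      iv <- activity_intervals(tr, threshold)
      c(fraction = total_active_fraction(iv, horizon),
        n_intervals = nrow(iv))
    }
  }
  set.seed(seed)
  train_seeds <- sample.int(.Machine$integer.max - 1, n_trains)
  rows <- vector("list", n_trains)
  failed <- 0
  for (i in seq_len(n_trains)) {
    train <- random_pulse_train(n_pulses, pulse_len, horizon,
                                seed = train_seeds[i])
    rec <- tryCatch(simulate_fun(train, threshold), error = function(e) {
      warning("realization ", i, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(rec)) { failed <- failed + 1; next }
    rows[[i]] <- data.frame(train_seed = train_seeds[i],
                            fraction = rec[["fraction"]],
                            n_intervals = rec[["n_intervals"]])
  }
  out <- do.call(rbind, rows)
  structure(out, threshold = threshold, params = params, failed = failed,
            seed = seed)
}

#' Integration/partitioning trade-off of the decay baseline
#'
#' Runs the pulse-train ensemble for each exponential-decay preset
#' (matched train seeds across presets), demonstrating the trade-off: slow
#' decay rates integrate history but lose temporal partitioning (few
#' disjoint intervals), fast rates partition but lose integration (active
#' fraction approaches the train's own on-time fraction).
#'
#' @param presets list of [decay_params()] (default [decay_presets()]).
#' @param n_trains,seed,n_pulses,pulse_len,horizon,dt_out as
#'   [ensemble_run()].
#' @return Named list of ensemble data frames, one per preset.
#' @export
decay_tradeoff_suite <- function(presets = decay_presets(),
                                 n_trains = 1000, seed = 1, n_pulses = 12,
                                 pulse_len = 5, horizon = 480,
                                 dt_out = 0.1) {
  lapply(presets, function(p)
    ensemble_run(p, n_trains = n_trains, seed = seed, n_pulses = n_pulses,
                 pulse_len = pulse_len, horizon = horizon,
                 dt_out = dt_out, threshold = activity_threshold(p)))
}
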