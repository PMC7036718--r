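# Stimulation protocols: random pulse trains, steps and two-pulse probes.
# Times are stated in minutes and converted to model units at simulation
# time via units_per_minute().

new_pulse_train <- function(onsets, pulse_len, amplitude, horizon,
                            seed = NA_integer_) {
  stopifnot(pulse_len >= 0, horizon > 0)
  onsets <- sort(as.numeric(onsets))
  if (length(onsets) && (min(onsets) < 0 ||
                         max(onsets) > horizon - pulse_len + 1e-9))
    stop("pulse onsets must lie within [0, horizon - pulse_len]")
  structure(list(onsets = onsets, pulse_len = pulse_len,
                 amplitude = amplitude, horizon = horizon, seed = seed),
            class = "pulse_train")
}

#' Random train of ligand pulses
#'
#' Generates a stimulation protocol of `n_pulses` pulses of length
#' `pulse_len` minutes randomly distributed over the horizon.  By default
#' the pulses are pairwise disjoint -- a perfusion protocol delivers
#' `n_pulses` distinct pulses -- sampled uniformly over all disjoint
#' arrangements by the order-statistics construction (uniform points in
#' the slack interval plus cumulative pulse offsets).  With
#' `allow_overlap = TRUE` onsets are drawn independently and overlapping
#' pulses merge into a single longer on-interval (the on/off indicator is
#' always the union of the pulse intervals).  The default geometry is the
#' twelve 5-min pulses over 480 min used throughout the signal-processing
#' analyses.
#'
#' @param n_pulses number of pulses.
#' @param pulse_len pulse length in minutes.
#' @param horizon protocol horizon in minutes.
#' @param amplitude total ligand level during a pulse; `NULL` means "fill in
#'   at simulation time" (the calibrated level giving 15% ligand-bound
#'   receptors, see [ligand_for_target_occupancy()]).
#' @param seed optional integer seed making the train reproducible.
#' @param allow_overlap sample onsets independently (overlaps merge).
#' @return A `pulse_train` object.
#' @export
random_pulse_train <- function(n_pulses = 12, pulse_len = 5, horizon = 480,
                               amplitude = NULL, seed = NULL,
                               allow_overlap = FALSE) {
  if (n_pulses * pulse_len > horizon)
    stop("infeasible protocol: n_pulses * pulse_len exceeds the horizon")
  if (!is.null(seed)) set.seed(seed)
  onsets <- if (n_pulses == 0) {
    numeric(0)
  } else if (allow_overlap) {
    runif(n_pulses, 0, horizon - pulse_len)
  } else {
    sort(runif(n_pulses, 0, horizon - n_pulses * pulse_len)) +
      (seq_len(n_pulses) - 1) * pulse_len
  }
  new_pulse_train(onsets, pulse_len, amplitude, horizon,
                  if (is.null(seed)) NA_integer_ else seed)
}

#' Two-pulse stimulation protocol
#'
#' Two pulses of `pulse_len` minutes separated by `gap` minutes, used to
#' probe dynamic transient memory (a second pulse arriving within the
#' memory lifetime prolongs the total activity).
#'
#' @param pulse_len pulse length in minutes.
#' @param gap inter-pulse interval in minutes (end of first to start of
#'   second); `gap = 0` merges the pulses.
#' @param amplitude ligand level during the pulses (`NULL` = calibrated).
#' @param horizon protocol horizon in minutes.
#' @param t_start onset of the first pulse in minutes.
#' @return A `pulse_train` object.
#' @export
two_pulse_protocol <- function(pulse_len = 5, gap = 10, amplitude = NULL,
                               horizon = NULL, t_start = 5) {
  if (gap < 0) stop("gap must be non-negative")
  onsets <- c(t_start, t_start + pulse_len + gap)
  if (is.null(horizon)) horizon <- max(onsets) + pulse_len + 120
  new_pulse_train(onsets, pulse_len, amplitude, horizon)
}

#' Single-step (one pulse) protocol
#'
#' @param t_on,t_off pulse start and end in minutes.
#' @param amplitude input level during the pulse (`NULL` = calibrated).
#' @param horizon protocol horizon in minutes.
#' @return A `pulse_train` object.
#' @export
step_protocol <- function(t_on = 5, t_off = 10, amplitude = NULL,
                          horizon = NULL) {
  stopifnot(t_off > t_on)
  if (is.null(horizon)) horizon <- t_off + 120
  new_pulse_train(t_on, t_off - t_on, amplitude, horizon)
}

#' Merged on-intervals of a pulse train
#'
#' @param train a `pulse_train`.
#' @return Two-column matrix of disjoint `[start, end)` on-intervals in
#'   minutes (the union of the pulse intervals).
#' @export
pulse_intervals <- function(train) {
  stopifnot(inherits(train, "pulse_train"))
  if (!length(train$onsets))
    return(matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("start", "end"))))
  s <- train$onsets
  e <- pmin(s + train$pulse_len, train$horizon)
  ms <- s[1]; me <- e[1]; out <- NULL
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) me <- max(me, e[i])
    else { out <- rbind(out, c(ms, me)); ms <- s[i]; me <- e[i] }
  }
  out <- rbind(out, c(ms, me))
  colnames(out) <- c("start", "end")
  out
}

#' On/off indicator of a pulse train
#'
#' @param train a `pulse_train`.
#' @param t times in minutes.
#' @return 0/1 vector, 1 when `t` falls inside a pulse.
#' @export
pulse_indicator <- function(train, t) {
  iv <- pulse_intervals(train)
  out <- numeric(length(t))
  for (k in seq_len(nrow(iv)))
    out[t >= iv[k, 1] & t < iv[k, 2]] <- 1
  out
}

# Piecewise-constant segments for the integrator, in model time units.
# Returns list(breaks, values): values[i] holds on (breaks[i-1], breaks[i]].
protocol_segments <- function(train, amplitude, horizon_min = NULL) {
  horizon <- if (is.null(horizon_min)) train$horizon
             else max(horizon_min, train$horizon)
  iv <- pulse_intervals(train)
  upm <- units_per_minute()
  breaks <- numeric(0); values <- numeric(0); t0 <- 0
  for (k in seq_len(nrow(iv))) {
    if (iv[k, 1] > t0) { breaks <- c(breaks, iv[k, 1]); values <- c(values, 0) }
    breaks <- c(breaks, iv[k, 2]); values <- c(values, amplitude)
    t0 <- iv[k, 2]
  }
  if (t0 < horizon || !length(breaks)) {
    breaks <- c(breaks, horizon); values <- c(values, 0)
  }
  list(breaks = breaks * upm, values = values)
}

#' Ligand level producing a target bound-receptor occupancy
#'
#' Solves the binding steady state `kon (1 - LRa) LT = koff LRa` for the
#' total ligand `LT` giving the requested steady-state fraction of
#' ligand-bound receptors.  The published pulse amplitude corresponds to
#' `target = 0.15`.
#'
#' @param params [toggle_params()] (only `kon`, `koff` are used).
#' @param target requested steady-state ligand-bound fraction, in (0, 1).
#' @return The ligand amplitude `LT`.
#' @export
ligand_for_target_occupancy <- function(params, target = 0.15) {
  if (target < 0 || target >= 1) stop("target occupancy must be in [0, 1)")
  params$koff * target / (params$kon * (1 - target))
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf(
    "Pulse train: %d pulse(s) of %g min over %g min (amplitude %s)\n",
    length(x$onsets), x$pulse_len, x$horizon,
    if (is.null(x$amplitude)) "calibrated" else format(x$amplitude)))
  invisible(x)
}

#' Serialize / restore a pulse train as JSON
#'
#' @param train a `pulse_train`.
#' @param path file path.
#' @return `read_pulse_train()` returns the restored `pulse_train`.
#' @export
write_pulse_train <- function(train, path) {
  jsonlite::write_json(unclass(train), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pulse_train
#' @export
read_pulse_train <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_pulse_train(x$onsets, x$pulse_len,
                  if (is.null(x$amplitude)) NULL else x$amplitude,
                  x$horizon, if (is.null(x$seed)) NA_integer_ else x$seed)
}
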