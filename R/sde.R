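# Stochastic simulation with multiplicative noise (Stratonovich, Heun
# predictor-corrector), wavelet dominant-frequency analysis of basal
# activity fluctuations, and the self-organized-criticality run.

#' Multiplicative-noise specification
#'
#' Stratonovich multiplicative noise with state-dependent amplitude
#' `sigma * sqrt(x (1 - x))` per noisy variable: the toggle variant puts
#' noise on every variable (published amplitude `sigma = 0.05`), the
#' compartment variant only on the membrane active fraction with intensity
#' `sigma_a^2 = 8e-4`.  The amplitude satisfies the inverse-square-root
#' scaling of relative fluctuations at small `x` and vanishes at the
#' domain boundaries.
#'
#' @param sigma noise amplitude; alternatively give the intensity
#'   `sigma2` (`sigma = sqrt(sigma2)`).
#' @param sigma2 noise intensity.
#' @param dt (initial) time step of the Heun scheme.
#' @param adaptive use the adaptive step-size rule: halve on a rejected
#'   step (increment above `inc_tol` or state outside `[0, 1]`), double
#'   after 10 accepted steps.
#' @param inc_tol per-step state-increment tolerance.
#' @param dt_min,dt_max step-size floor and ceiling.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(sigma = NULL, sigma2 = NULL, dt = 0.01,
                       adaptive = TRUE, inc_tol = 0.01, dt_min = 1e-3,
                       dt_max = 0.1) {
  if (is.null(sigma)) {
    if (is.null(sigma2)) stop("give sigma or sigma2")
    sigma <- sqrt(sigma2)
  }
  stopifnot(sigma >= 0, dt > 0)
  structure(list(sigma = sigma, dt = dt, adaptive = adaptive,
                 inc_tol = inc_tol, dt_min = dt_min, dt_max = dt_max),
            class = "noise_spec")
}

#' Stochastic model simulation
#'
#' Integrates the toggle switch or the compartment model as a Stratonovich
#' SDE with multiplicative noise using the Heun predictor-corrector
#' scheme.  With zero noise intensity the run reduces to the deterministic
#' trajectory (up to the scheme's discretization error).
#'
#' @param model `"toggle"` (dynamic ligand, noise on every state) or
#'   `"compartment"` (noise on the membrane active fraction only).
#' @param params matching parameter object.
#' @param noise a [noise_spec()].
#' @param protocol optional `pulse_train` (ligand input); `NULL` = no
#'   input.
#' @param init initial state; `NULL` = basal fixed point.
#' @param horizon horizon in minutes.
#' @param dt_out output sampling interval in minutes.
#' @param seed optional RNG seed.
#' @param dynamic_krec compartment model only.
#' @param amplitude protocol amplitude override.
#' @return A `ghost_trajectory` with attributes `n_steps`, `n_rejected`,
#'   `n_clamped`.
#' @export
sde_simulate <- function(model = c("toggle", "compartment"), params,
                         noise, protocol = NULL, init = NULL,
                         horizon = NULL, dt_out = 0.1, seed = NULL,
                         dynamic_krec = FALSE, amplitude = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(noise, "noise_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(protocol)) {
    if (is.null(horizon)) stop("need a protocol or an explicit horizon")
    protocol <- new_pulse_train(numeric(0), 0, 0, horizon)
  }
  if (is.null(horizon)) horizon <- protocol$horizon
  if (is.null(amplitude)) amplitude <- protocol$amplitude
  if (is.null(amplitude))
    amplitude <- ligand_for_target_occupancy(params)
  seg <- protocol_segments(protocol, amplitude, horizon)
  if (is.null(init)) init <- default_init(model, params)
  pv <- if (model == "compartment")
    as_param_vector(params, dynamic_krec = dynamic_krec)
  else as_param_vector(params)
  upm <- units_per_minute()
  out_times <- seq(0, horizon, by = dt_out) * upm
  res <- .sde_heun_cpp(model_id(model), pv, unname(init), seg$breaks,
                       seg$values, out_times, noise$sigma,
                       if (model == "toggle") 0L else 1L, noise$adaptive,
                       noise$dt, noise$inc_tol, noise$dt_min,
                       noise$dt_max)
  idx <- findInterval(out_times, seg$breaks, left.open = TRUE) + 1
  u <- seg$values[pmin(idx, length(seg$values))]
  tr <- new_trajectory(model, out_times, res$states, u, protocol, params,
                       seed = if (is.null(seed)) NA_integer_ else seed)
  attr(tr, "n_steps") <- res$n_steps
  attr(tr, "n_rejected") <- res$n_rejected
  attr(tr, "n_clamped") <- res$n_clamped
  tr
}

#' Dominant frequency of a time series (Morlet wavelet)
#'
#' Computes a continuous Morlet wavelet transform of the (linearly
#' detrended) trace, averages the wavelet power over time at each scale,
#' and reports the frequency of the maximal time-averaged power.
#'
#' @param x uniformly sampled trace (length at least 512).
#' @param dt sampling interval (any time unit).
#' @param omega0 Morlet angular frequency parameter.
#' @param n_scales number of logarithmically spaced scales.
#' @param lowest_period,largest_period analysed period range, in time
#'   units (defaults: `4 dt` to a third of the record).
#' @return List `frequency` (cycles per time unit), `period`, `power`
#'   (data frame `period`, `frequency`, `mean_power`).
#' @export
dominant_frequency <- function(x, dt, omega0 = 6, n_scales = 64,
                               lowest_period = NULL,
                               largest_period = NULL) {
  n <- length(x)
  if (n < 512) stop("need at least 512 samples")
  if (var(x) < 1e-16) {
    warning("constant trace: dominant frequency undefined")
    return(list(frequency = NA_real_, period = NA_real_, power = NULL))
  }
  tt <- seq_len(n)
  x <- residuals(lm(x ~ tt)) # linear detrend
  if (is.null(lowest_period)) lowest_period <- 4 * dt
  if (is.null(largest_period)) largest_period <- n * dt / 3
  # Fourier angular frequencies and the Morlet scale-period relation
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  periods <- exp(seq(log(lowest_period), log(largest_period),
                     length.out = n_scales))
  scales <- periods / fourier_factor
  np <- stats::nextn(n, 2)
  xf <- fft(c(x, rep(0, np - n)))
  w <- 2 * pi * c(0:(np / 2), -(np / 2 - 1):-1) / (np * dt)
  mean_power <- vapply(scales, function(s) {
    psi <- sqrt(2 * pi * s / dt) * pi^(-0.25) *
      exp(-0.5 * (s * w - omega0)^2) * (w > 0)
    wt <- fft(xf * psi, inverse = TRUE)[seq_len(n)] / np
    # discard the cone-of-influence edges (about sqrt(2) scales)
    m <- min(n %/% 4, ceiling(sqrt(2) * s / dt))
    mean(Mod(wt[(m + 1):(n - m)])^2)
  }, 1)
  i <- which.max(mean_power)
  list(frequency = 1 / periods[i], period = periods[i],
       power = data.frame(period = periods, frequency = 1 / periods,
                          mean_power = mean_power))
}

#' Dominant fluctuation frequency across receptor concentrations
#'
#' For each total receptor concentration `RT`, simulates `n_real`
#' stochastic basal-activity traces of the compartment model at zero
#' ligand (from the basal fixed point) and averages the dominant wavelet
#' frequency of the membrane active fraction.  Near the saddle-node the
#' nullclines align, fluctuations slow down, and the dominant frequency is
#' minimal; it increases into the monostable regime -- the readout a
#' fluctuation-sensing recycling actuator could exploit.
#'
#' @param RT_values receptor concentrations to scan (monostable side of
#'   the fold).
#' @param params [compartment_params()] (its `RT` is overridden).
#' @param noise a [noise_spec()] (published intensity 8e-4).
#' @param n_real realizations per concentration.
#' @param horizon trace length in minutes.
#' @param dt_out sampling interval in minutes.
#' @param seed master seed.
#' @return Data frame `RT`, `frequency` (mean over realizations, cycles
#'   per model time unit), `frequency_sd`.
#' @export
frequency_vs_RT_scan <- function(RT_values, params = compartment_params(),
                                 noise = noise_spec(sigma2 = 8e-4),
                                 n_real = 50, horizon = 200, dt_out = 0.05,
                                 seed = 1) {
  if (noise$sigma <= 0)
    stop("zero-noise control: no fluctuations to analyse")
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1,
                             length(RT_values) * n_real),
                  nrow = length(RT_values))
  upm <- units_per_minute()
  rows <- lapply(seq_along(RT_values), function(i) {
    pp <- params; pp$RT <- RT_values[i]; pp$LT <- 0
    init <- default_init("compartment", pp)
    fr <- vapply(seq_len(n_real), function(r) {
      tr <- sde_simulate("compartment", pp, noise, horizon = horizon,
                         dt_out = dt_out, init = init,
                         seed = seeds[i, r], amplitude = 0)
      dominant_frequency(tr$states[, "RaPM"], dt_out * upm)$frequency
    }, 1)
    data.frame(RT = RT_values[i], frequency = mean(fr),
               frequency_sd = sd(fr))
  })
  do.call(rbind, rows)
}

#' Self-organized maintenance of critical organization
#'
#' Simulates the compartment model with ligand-bound receptor degradation
#' under a train of stimulus pulses, once with the dynamic recycling law
#' (recycling up-regulated as receptors are lost, holding the system near
#' the saddle-node) and once with fixed recycling (the control, which
#' drifts into the monostable regime and loses its post-pulse transient
#' memory pulse over pulse).
#'
#' @param params [compartment_params()] (degradation active by default,
#'   `kdeg = 0.2`).
#' @param train a `pulse_train`; the default is four 5-min pulses 90 min
#'   apart.
#' @param dt_out sampling interval in minutes.
#' @return List `dynamic`, `fixed`: the two trajectories.
#' @export
self_organized_run <- function(params = compartment_params(),
                               train = NULL, dt_out = 0.1) {
  if (is.null(train))
    train <- new_pulse_train(c(30, 120, 210, 300), 5, 0.2926, 400)
  if (is.null(train$amplitude) || train$amplitude == 0)
    train$amplitude <- 0.2926 # published stimulus ligand level
  list(dynamic = simulate_model("compartment", params, train,
                                dt_out = dt_out, dynamic_krec = TRUE),
       fixed = simulate_model("compartment", params, train,
                              dt_out = dt_out, dynamic_krec = FALSE))
}
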