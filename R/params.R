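#' Parameters of the receptor-phosphatase toggle switch
#'
#' Rate constants of the two-component double-negative-feedback switch
#' between active receptor `Ra` and the deactivating phosphatase `Pa`.
#' Defaults are the published set for the receptor network.  `gammaDNF_hat`
#' is the specific reactivity of the phosphatase towards the receptor
#' (proportional to the total phosphatase/receptor concentration ratio) and
#' is the bifurcation parameter; the canonical organizations are 2.5
#' (irreversible bistable), 2.957 (critical), 3.5 (reversible bistable) and
#' 4.3 (monostable), see [organization_gamma()].
#'
#' @param gammaDNF_hat specific reactivity (dimensionless), the bifurcation
#'   parameter.
#' @param LT total ligand level (input amplitude in dynamic-ligand mode).
#' @param alpha1,alpha2,alpha3 autonomous, autocatalytic and
#'   ligand-bound-induced activation rate constants.
#' @param betaDNF_hat receptor-induced phosphatase inhibition constant
#'   (dimensionless).
#' @param k1 phosphatase time-scale constant; does not affect steady states.
#' @param k21 phosphatase inactivation/activation ratio k2/k1.
#' @param kR receptor time-scale constant; does not affect steady states.
#' @param kon,koff ligand binding and unbinding constants.
#' @return An object of class `toggle_params`.
#' @export
toggle_params <- function(gammaDNF_hat = 2.957, LT = 0, alpha1 = 0.0017,
                          alpha2 = 0.3, alpha3 = 1.0,
                          betaDNF_hat = 36.0558, k1 = 0.01, k21 = 0.5,
                          kR = 0.8, kon = 0.003, koff = 0.01668) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
            betaDNF_hat = betaDNF_hat, gammaDNF_hat = gammaDNF_hat,
            k1 = k1, k21 = k21, kR = kR, kon = kon, koff = koff, LT = LT)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("toggle parameters must be finite and non-negative")
  if (k21 <= 0) stop("k21 must be positive")
  structure(p, class = "toggle_params")
}

#' Canonical toggle-switch organizations
#'
#' Maps an organization label to its `gammaDNF_hat` value: bistable
#' (irreversible) 2.5, critical 2.957, reversible (bistable) 3.5,
#' monostable 4.3.
#'
#' @param label one of `"bistable"`, `"critical"`, `"reversible"`,
#'   `"monostable"`.
#' @return The corresponding `gammaDNF_hat` value.
#' @export
organization_gamma <- function(label = c("bistable", "critical",
                                         "reversible", "monostable")) {
  label <- match.arg(label)
  c(bistable = 2.5, critical = 2.957, reversible = 3.5,
    monostable = 4.3)[[label]]
}

#' Parameters of the two-compartment EGFR trafficking model
#'
#' Seven-species plasma-membrane/endosome model coupling the toggle switch
#' to vesicular trafficking (internalization, recycling, degradation) and
#' two further phosphatases.  Defaults are the published set; `RT` (total
#' receptor concentration) is the bifurcation parameter, critically
#' organized at 1.3499 for the default recycling rate.
#'
#' @param RT total receptor concentration (bifurcation parameter).
#' @param LT total ligand level.
#' @param gammaDNF,gammaNF,gammaNR specific reactivities of the
#'   double-negative-feedback, negative-feedback and negative-regulation
#'   phosphatases.
#' @param betaDNF receptor-induced phosphatase inhibition constant.
#' @param k1,k21,alpha1,alpha2,alpha3,kon,koff as in [toggle_params()].
#' @param kin internalization rate of active receptors.
#' @param kini inactive-receptor internalization multiplier.
#' @param krec endosomal recycling rate.
#' @param kdeg degradation multiplier for internalized ligand-bound
#'   receptors.
#' @param PDNFT,PNFT,PNRT total phosphatase concentrations.
#' @param RT_asymp large-`krec` asymptote of the fold's `RT` value, used by
#'   the dynamic recycling law.
#' @param sat saturation level of the dynamic recycling multiplier.
#' @return An object of class `compartment_params`.
#' @export
compartment_params <- function(RT = 1.3499, LT = 0, gammaDNF = 3.0,
                               gammaNF = 3.0, gammaNR = 0.001,
                               betaDNF = 36.0558, k1 = 0.01, k21 = 0.5,
                               kin = 0.02, kini = 0.2, krec = 0.042,
                               kdeg = 0.2, PDNFT = 1.0, PNFT = 1.0,
                               PNRT = 1.0, alpha1 = 0.0017, alpha2 = 0.3,
                               alpha3 = 1.0, kon = 0.003, koff = 0.01668,
                               RT_asymp = 1.086, sat = 2.5) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
            gammaDNF = gammaDNF, gammaNF = gammaNF, gammaNR = gammaNR,
            betaDNF = betaDNF, k1 = k1, k21 = k21, kin = kin, kini = kini,
            krec = krec, kdeg = kdeg, RT = RT, PDNFT = PDNFT, PNFT = PNFT,
            PNRT = PNRT, kon = kon, koff = koff, RT_asymp = RT_asymp,
            sat = sat, LT = LT)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("compartment parameters must be finite and non-negative")
  if (RT <= 0) stop("RT must be positive")
  structure(p, class = "compartment_params")
}

#' Parameters of the exponential-decay baseline model
#'
#' Relaxation model dRa/dt = I alpha (RT - Ra) - beta Ra, with `I` the
#' growth-factor pulse indicator.  The five published `(beta, RT)` pairs are
#' available through [decay_presets()]; each `RT` is calibrated so the
#' activated steady amplitude matches the critically organized toggle.
#'
#' @param beta decay constant.
#' @param RT total concentration.
#' @param alpha activation constant.
#' @param I input level used when no protocol is supplied (1 during a
#'   pulse, 0 otherwise).
#' @return An object of class `decay_params`.
#' @export
decay_params <- function(beta, RT, alpha = 0.023, I = 1) {
  if (any(c(alpha, beta, RT) < 0)) stop("decay parameters must be >= 0")
  structure(list(alpha = alpha, beta = beta, RT = RT, I = I),
            class = "decay_params")
}

#' @rdname decay_params
#' @return `decay_presets()` returns a named list of the five published
#'   `decay_params` presets.
#' @export
decay_presets <- function() {
  tab <- list(c(1.5e-4, 0.8206), c(5.5e-4, 0.8351), c(0.001, 0.8513),
              c(0.0035, 0.9416), c(0.01, 1.1765))
  out <- lapply(tab, function(z) decay_params(beta = z[1], RT = z[2]))
  names(out) <- vapply(tab, function(z) paste0("beta=", format(z[1])), "")
  out
}

# Parameter vectors in the fixed layout the compiled models expect.
as_param_vector <- function(params, ...) UseMethod("as_param_vector")

#' @export
as_param_vector.toggle_params <- function(params, ...) {
  with(params, c(alpha1, alpha2, alpha3, betaDNF_hat, gammaDNF_hat,
                 k1, k21, kR, kon, koff))
}

#' @export
as_param_vector.compartment_params <- function(params,
                                               dynamic_krec = FALSE, ...) {
  with(params, c(alpha1, alpha2, alpha3, gammaDNF, gammaNF, gammaNR,
                 betaDNF, k1, k21, kin, kini, krec, kdeg, RT, PDNFT,
                 PNFT, PNRT, kon, koff, RT_asymp, sat,
                 as.numeric(dynamic_krec)))
}

#' @export
as_param_vector.decay_params <- function(params, ...) {
  with(params, c(alpha, beta, RT))
}

#' @export
print.toggle_params <- function(x, ...) {
  cat("Toggle-switch parameters (gammaDNF_hat =", x$gammaDNF_hat, ")\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.compartment_params <- function(x, ...) {
  cat("Compartment-model parameters (RT =", x$RT, ", krec =", x$krec, ")\n")
  print(unlist(unclass(x)))
  invisible(x)
}
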