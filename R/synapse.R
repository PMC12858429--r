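#' Synapse kinetics
#'
#' Rise/decay time constants and sign of a beta-function conductance synapse.
#'
#' @param tau_rise rise time constant (ms), `> 0`.
#' @param tau_decay decay time constant (ms), `> 0`.
#' @param sign `"excitatory"` or `"inhibitory"`; decides which reversal
#'   potential the conductance acts through.
#' @return An object of class `synapse_kinetics`.
#' @export
synapse_kinetics <- function(tau_rise, tau_decay,
                             sign = c("excitatory", "inhibitory")) {
  sign <- match.arg(sign)
  if (!(tau_rise > 0 && tau_decay > 0)) {
    stop("synapse time constants must be positive (tau_rise=", tau_rise,
         ", tau_decay=", tau_decay, ")")
  }
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay, sign = sign),
            class = "synapse_kinetics")
}

#' Peak time of the normalized beta kernel
#'
#' Closed form of the lag at which the difference of exponentials
#' `exp(-s/tau_decay) - exp(-s/tau_rise)` is maximal:
#' `s* = tau_d tau_r / (tau_d - tau_r) * log(tau_d / tau_r)`.
#' For `tau_rise == tau_decay` the alpha-function limit gives `s* = tau`.
#'
#' @param tau_rise,tau_decay time constants (ms).
#' @return peak lag (ms).
#' @export
beta_peak_time <- function(tau_rise, tau_decay) {
  if (tau_rise == tau_decay) return(tau_rise)
  tau_decay * tau_rise / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

#' Normalization constant of the beta kernel
#'
#' Value of `exp(-s*/tau_decay) - exp(-s*/tau_rise)` at the peak lag, i.e. the
#' factor that rescales the raw difference of exponentials so its maximum is
#' exactly 1. In the equal-time-constant (alpha) limit the peak of
#' `(s/tau) exp(1 - s/tau)` is already 1, so the constant is 1.
#'
#' @inheritParams beta_peak_time
#' @return dimensionless peak value of the unnormalized kernel.
#' @export
beta_peak_value <- function(tau_rise, tau_decay) {
  if (tau_rise == tau_decay) return(1)
  s <- beta_peak_time(tau_rise, tau_decay)
  exp(-s / tau_decay) - exp(-s / tau_rise)
}

#' Peak-normalized beta-function synaptic conductance
#'
#' Conductance at time `t` of a synaptic event with onset `t0` and peak weight
#' `W`: `W * (exp(-(t-t0)/tau_decay) - exp(-(t-t0)/tau_rise)) / eta`, where
#' `eta` is the analytic peak of the bracketed difference, so
#' `max_t g(t) == W` exactly (a weight of 1.0 peaks at 1 nS). When
#' `tau_rise == tau_decay` the continuous alpha-function limit
#' `W * (s/tau) * exp(1 - s/tau)` is used.
#'
#' @param t evaluation time(s) (ms), `>= onset`.
#' @param onset event onset t0 (ms).
#' @param weight peak conductance W (nS), `>= 0`.
#' @param kinetics a [synapse_kinetics()] (or list with `tau_rise`,
#'   `tau_decay`).
#' @return conductance (nS), same length as `t`.
#' @export
beta_conductance <- function(t, onset = 0, weight = 1, kinetics) {
  tr <- kinetics$tau_rise
  td <- kinetics$tau_decay
  if (!(tr > 0 && td > 0)) stop("non-positive synapse time constant")
  if (any(t < onset)) stop("beta_conductance evaluated before event onset")
  s <- t - onset
  if (tr == td) {
    weight * (s / tr) * exp(1 - s / tr)
  } else {
    weight * (exp(-s / td) - exp(-s / tr)) / beta_peak_value(tr, td)
  }
}
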