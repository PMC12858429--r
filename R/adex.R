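#' Adaptive exponential integrate-and-fire (AdEx) neuron parameters
#'
#' Bundles every constant of the AdEx membrane, adaptation and reset
#' equations for one neuron class. Membrane dynamics follow
#' \deqn{C \, dV_m/dt = -g_L (V_m - E_L) + g_L \Delta_T e^{(V_m - V_{th})/\Delta_T}
#'   - g_e(t)(V_m - E_e) - g_i(t)(V_m - E_i) - w + I_{bias},}
#' \deqn{\tau_w \, dw/dt = a (V_m - E_L) - w,}
#' with reset: when \eqn{V_m > 0} mV, \eqn{V_m \to V_{reset}},
#' \eqn{w \to w + b}, and the neuron is refractory for \eqn{t_{ref}}.
#'
#' @param C membrane capacitance (pF).
#' @param gL leak conductance (nS).
#' @param EL resting (leak reversal) potential (mV).
#' @param DeltaT spike sharpness factor (mV).
#' @param Vth spike-initiation threshold of the exponential term (mV).
#' @param tau_w adaptation time constant (ms).
#' @param a subthreshold adaptation conductance (nS).
#' @param b spike-triggered adaptation increment (pA).
#' @param Vreset post-spike reset potential (mV).
#' @param t_ref absolute refractory period (ms).
#' @param Ee excitatory synaptic reversal potential (mV).
#' @param Ei inhibitory synaptic reversal potential (mV).
#' @param Ibias constant bias current (pA); per-step Gaussian noise with
#'   SD equal to `|Ibias|` is added on top of it during network simulation.
#' @param mode `"tonic"` or `"bursting"`; a label describing the firing
#'   pattern the parameter set is tuned to produce.
#'
#' @return An object of class `adex_params` (a named list).
#' @seealso [adex_tonic()], [adex_bursting()], [step_neuron()]
#' @export
adex_params <- function(C = 200, gL = 10, EL = -70, DeltaT = 2, Vth = -50,
                        tau_w = 100, a = 2, b = 10, Vreset = -58, t_ref = 2,
                        Ee = 0, Ei = -75, Ibias = 0,
                        mode = c("tonic", "bursting")) {
  mode <- match.arg(mode)
  p <- list(C = C, gL = gL, EL = EL, DeltaT = DeltaT, Vth = Vth,
            tau_w = tau_w, a = a, b = b, Vreset = Vreset, t_ref = t_ref,
            Ee = Ee, Ei = Ei, Ibias = Ibias, mode = mode)
  class(p) <- "adex_params"
  validate_adex_params(p)
  p
}

validate_adex_params <- function(p) {
  stopifnot(p$C > 0, p$gL >= 0, p$tau_w > 0, p$t_ref >= 0, p$DeltaT > 0)
  if (!(p$Ei < p$EL && p$EL < p$Ee)) {
    stop("AdEx parameters require Ei < EL < Ee, got Ei=", p$Ei,
         ", EL=", p$EL, ", Ee=", p$Ee)
  }
  if (p$Vreset > p$Vth + p$DeltaT * 20) {
    stop("Vreset far above threshold: neuron would spike immediately forever")
  }
  invisible(p)
}

#' Default tonic-mode AdEx parameter set
#'
#' Regular-spiking set used for tonically firing neurons (weak spike-triggered
#' adaptation, sub-threshold reset). Starting point is the classical
#' regular-spiking AdEx parameterization; `a`, `b`, `tau_w` were tuned so a
#' population under its rated drive fires tonically in the 10-100 Hz range.
#'
#' @param ... overrides passed on to [adex_params()].
#' @return `adex_params` object with `mode = "tonic"`.
#' @export
adex_tonic <- function(...) {
  args <- utils::modifyList(
    list(C = 200, gL = 10, EL = -70, DeltaT = 2, Vth = -50,
         tau_w = 100, a = 2, b = 10, Vreset = -58, t_ref = 2,
         mode = "tonic"),
    list(...))
  do.call(adex_params, args)
}

#' Default bursting-mode AdEx parameter set
#'
#' Intrinsically bursting set: the reset potential sits above the exponential
#' threshold so each spike re-triggers the next until the slowly accumulating
#' adaptation current terminates the burst; the long `tau_w` sets the
#' inter-burst interval and hence the 2-3 Hz network rhythm target.
#'
#' @param ... overrides passed on to [adex_params()].
#' @return `adex_params` object with `mode = "bursting"`.
#' @export
adex_bursting <- function(...) {
  args <- utils::modifyList(
    list(C = 200, gL = 10, EL = -58, DeltaT = 2, Vth = -50,
         tau_w = 280, a = 4, b = 70, Vreset = -46, t_ref = 2,
         mode = "bursting"),
    list(...))
  do.call(adex_params, args)
}

#' Create a neuron state
#'
#' @param Vm membrane potential (mV).
#' @param w adaptation current (pA).
#' @param refractory_remaining remaining refractory time (ms), `>= 0`.
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(Vm = -70, w = 0, refractory_remaining = 0) {
  stopifnot(is.finite(Vm), refractory_remaining >= 0)
  structure(list(Vm = Vm, w = w,
                 refractory_remaining = refractory_remaining),
            class = "neuron_state")
}

#' One forward-Euler step of a single AdEx neuron
#'
#' Reference (pure-R) integrator for one neuron, used for unit-level checks
#' and as the fine-step oracle against the compiled network engine. The
#' exponential argument `(Vm - Vth)/DeltaT` is capped (default +20) before
#' exponentiation so the between-threshold-and-reset excursion cannot
#' overflow; spike detection itself uses the plain `Vm > 0 mV` rule.
#'
#' @param state a [neuron_state()].
#' @param params an [adex_params()].
#' @param g_exc,g_inh total excitatory / inhibitory synaptic conductance (nS),
#'   both `>= 0`.
#' @param noise additive current noise for this step (pA).
#' @param dt step size (ms), `> 0`.
#' @param exp_arg_cap cap on the exponential argument.
#' @return A list with the updated `state` and logical `spike`.
#' @export
step_neuron <- function(state, params, g_exc = 0, g_inh = 0, noise = 0,
                        dt = 0.1, exp_arg_cap = 20) {
  stopifnot(dt > 0, g_exc >= 0, g_inh >= 0)
  p <- params
  Vm <- state$Vm
  w <- state$w

  if (state$refractory_remaining > 0) {
    # clamped at Vreset; adaptation keeps relaxing, only the timer counts down
    w <- w + dt * (p$a * (Vm - p$EL) - w) / p$tau_w
    ref <- max(0, state$refractory_remaining - dt)
    return(list(state = neuron_state(p$Vreset, w, ref), spike = FALSE))
  }

  arg <- min((Vm - p$Vth) / p$DeltaT, exp_arg_cap)
  dV <- (-p$gL * (Vm - p$EL) + p$gL * p$DeltaT * exp(arg) -
           g_exc * (Vm - p$Ee) - g_inh * (Vm - p$Ei) - w +
           p$Ibias + noise) / p$C
  Vm_new <- Vm + dt * dV
  w_new <- w + dt * (p$a * (Vm - p$EL) - w) / p$tau_w

  if (!is.finite(Vm_new)) {
    stop("non-finite membrane potential during integration (Vm=", Vm,
         ", dV=", dV, ")")
  }

  if (Vm_new > 0) {
    list(state = neuron_state(p$Vreset, w_new + p$b, p$t_ref), spike = TRUE)
  } else {
    list(state = neuron_state(Vm_new, w_new, 0), spike = FALSE)
  }
}

#' Sample bias-current noise
#'
#' One Gaussian sample with mean 0 pA and standard deviation equal to the
#' absolute bias current, drawn per neuron per step. Samples may be negative
#' (transiently inhibitory) or positive.
#'
#' @param Ibias bias current (pA); the noise SD is `abs(Ibias)`.
#' @param n number of samples.
#' @return numeric vector of length `n` (pA).
#' @export
draw_noise <- function(Ibias, n = 1) {
  if (Ibias == 0) return(rep(0, n))
  stats::rnorm(n, mean = 0, sd = abs(Ibias))
}

#' Integrate a single neuron under constant input (reference path)
#'
#' Repeatedly applies [step_neuron()]; used by tests as a slow but transparent
#' oracle for the compiled engine and for mode (tonic/bursting) checks.
#'
#' @param params [adex_params()].
#' @param duration total time (ms).
#' @param dt step (ms).
#' @param I constant input current (pA) added to `Ibias`.
#' @param g_exc,g_inh constant conductances (nS).
#' @return numeric vector of spike times (ms).
#' @export
integrate_single_neuron <- function(params, duration, dt = 0.1, I = 0,
                                    g_exc = 0, g_inh = 0) {
  st <- neuron_state(Vm = params$EL, w = 0)
  n_steps <- round(duration / dt)
  spikes <- numeric(0)
  for (k in seq_len(n_steps)) {
    out <- step_neuron(st, params, g_exc = g_exc, g_inh = g_inh,
                       noise = I, dt = dt)
    st <- out$state
    if (out$spike) spikes <- c(spikes, k * dt)
  }
  spikes
}
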