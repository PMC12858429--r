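# Shared fixtures: micro-networks and synthetic rhythm traces, built in code.

kin_exc <- function(tau_rise = 0.5, tau_decay = 4)
  synapse_kinetics(tau_rise, tau_decay, "excitatory")
kin_inh <- function(tau_rise = 0.5, tau_decay = 6)
  synapse_kinetics(tau_rise, tau_decay, "inhibitory")

# two-population micro network: n_pre driven MNP_F neurons projecting to
# n_post undriven MNP_E neurons (labels reused for structural tests only)
micro_network <- function(n_pre = 2, n_post = 3, p_connect = 1,
                          weight = 2, drive = 0, sign = "excitatory") {
  kin <- if (sign == "excitatory") kin_exc() else kin_inh()
  network_config(
    populations = list(
      population_spec("MNP_F", n_pre, drive_mean = drive),
      population_spec("MNP_E", n_post)),
    projections = list(
      projection("MNP_F", "MNP_E", p_connect = p_connect,
                 weight_mean = weight, weight_sd = 0, kinetics = kin_exc())))
}

# single driven neuron as a network (for engine-level single-cell runs)
single_neuron_net <- function(drive = 0, mode = "tonic", ...) {
  population_spec_args <- list(name = "MNP_F", n = 1, drive_mean = drive)
  p <- population_spec("MNP_F", 1, drive_mean = drive,
                       bursting_fraction = if (mode == "bursting") 1 else 0,
                       params_tonic = adex_tonic(...),
                       params_bursting = adex_bursting(...))
  network_config(list(p), list())
}

# synthetic rate_trace on a dt grid
make_trace <- function(rate, dt_ms = 1, population = "MNP_F") {
  structure(list(population = population,
                 t = seq_along(rate) * dt_ms, rate = rate,
                 max_inst_rate = max(rate), rescale_factor = 1,
                 n_spikes = NA_integer_, dt_ms = dt_ms),
            class = "rate_trace")
}

# antiphase sinusoid pair with given period (ms)
sine_pair <- function(period = 1000, duration = 10000, dt_ms = 1,
                      offset = 1, amp = 1) {
  t <- seq(dt_ms, duration, by = dt_ms)
  f <- offset + amp * sin(2 * pi * t / period)
  e <- offset - amp * sin(2 * pi * t / period)
  list(flexor = make_trace(f, dt_ms, "MNP_F"),
       extensor = make_trace(e, dt_ms, "MNP_E"), t = t)
}

# brute-force peak enumeration oracle: all strict local maxima filtered by
# height/prominence/distance, resolving distance conflicts by height order
brute_peaks <- function(x, t, min_height_fraction = 0.4,
                        min_distance = 1000, prominence = 0.1) {
  idx <- which(diff(sign(diff(x))) < 0) + 1
  xn <- x / max(x)
  prom <- vapply(idx, function(p) {
    lo <- if (any(xn[1:p][-p] > xn[p])) max(which(xn[1:p][-p] > xn[p])) else 1
    hi_candidates <- which(xn[(p + 1):length(xn)] > xn[p])
    hi <- if (length(hi_candidates)) p + min(hi_candidates) else length(xn)
    xn[p] - max(min(xn[lo:p]), min(xn[p:hi]))
  }, 0)
  idx <- idx[xn[idx] >= min_height_fraction & prom >= prominence]
  ord <- idx[order(-x[idx], idx)]
  sel <- integer(0)
  for (i in ord)
    if (!length(sel) || all(abs(t[i] - t[sel]) >= min_distance))
      sel <- c(sel, i)
  sort(t[sel])
}
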