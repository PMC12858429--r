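POP_NAMES <- c("RG_F", "RG_E", "V1RG", "V2b", "V2a_F", "V2a_E",
               "V0c_F", "V0c_E", "Ia_F", "Ia_E", "RC_F", "RC_E",
               "MNP_F", "MNP_E")

# neurotransmitter class per population; RG populations are mixed and their
# outgoing sign is fixed by the projection's pre_subset
POP_SIGN <- c(RG_F = "mixed", RG_E = "mixed",
              V1RG = "inhibitory", V2b = "inhibitory",
              V2a_F = "excitatory", V2a_E = "excitatory",
              V0c_F = "excitatory", V0c_E = "excitatory",
              Ia_F = "inhibitory", Ia_E = "inhibitory",
              RC_F = "inhibitory", RC_E = "inhibitory",
              MNP_F = "excitatory", MNP_E = "excitatory")

# V1-derived populations: targets of disease-stage projection loss
V1_POPS <- c("V1RG", "Ia_F", "Ia_E", "RC_F", "RC_E")

#' Population specification
#'
#' @param name population label; one of the canonical CPG population names
#'   (`RG_F`, `RG_E`, `V1RG`, `V2b`, `V2a_F/E`, `V0c_F/E`, `Ia_F/E`,
#'   `RC_F/E`, `MNP_F/E`).
#' @param n neuron count, `>= 1`.
#' @param excitatory_fraction fraction of excitatory neurons (rhythm
#'   generators mix excitatory and inhibitory neurons 4:1; single-class
#'   populations use 1 or 0).
#' @param bursting_fraction fraction of neurons in bursting mode; exactly
#'   `round(bursting_fraction * n)` neurons are assigned bursting parameters.
#' @param drive_mean mean descending/tonic drive current (pA); 0 if the
#'   population is not driven. Per-neuron biases are drawn from
#'   `Normal(drive_mean, drive_sd_fraction * drive_mean)`.
#' @param params_tonic,params_bursting [adex_params()] templates for the two
#'   firing modes.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(name, n, excitatory_fraction = 1,
                            bursting_fraction = 0, drive_mean = 0,
                            params_tonic = adex_tonic(),
                            params_bursting = adex_bursting()) {
  stopifnot(n >= 1,
            excitatory_fraction >= 0, excitatory_fraction <= 1,
            bursting_fraction >= 0, bursting_fraction <= 1)
  if (drive_mean < 0) stop("negative drive mean for population ", name)
  structure(list(name = name, n = as.integer(n),
                 excitatory_fraction = excitatory_fraction,
                 bursting_fraction = bursting_fraction,
                 drive_mean = drive_mean,
                 params_tonic = params_tonic,
                 params_bursting = params_bursting),
            class = "population_spec")
}

#' Projection specification
#'
#' A probabilistic all-to-all wiring rule between two populations: each
#' ordered (pre, post) neuron pair is connected independently with
#' probability `p_connect` (at most one synapse per pair; autapses excluded
#' within a population); each realized synapse draws its peak conductance
#' from `Normal(weight_mean, weight_sd)` clipped at 0.
#'
#' @param pre,post population names.
#' @param p_connect connection probability in `[0, 1]`.
#' @param weight_mean,weight_sd weight distribution (nS), `weight_sd >= 0`.
#' @param kinetics a [synapse_kinetics()] (carries the synaptic sign).
#' @param delay conduction + synaptic delay (ms).
#' @param pre_subset `"all"`, `"excitatory"` or `"inhibitory"`: which neurons
#'   of a mixed population (the RGs) act as the presynaptic pool.
#' @return An object of class `projection`.
#' @export
projection <- function(pre, post, p_connect, weight_mean, weight_sd,
                       kinetics, delay = 1,
                       pre_subset = c("all", "excitatory", "inhibitory")) {
  pre_subset <- match.arg(pre_subset)
  stopifnot(p_connect >= 0, p_connect <= 1, weight_sd >= 0, delay > 0)
  structure(list(pre = pre, post = post, p_connect = p_connect,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 kinetics = kinetics, delay = delay,
                 pre_subset = pre_subset),
            class = "projection")
}

#' Network configuration
#'
#' The single declarative object that scenario transforms operate on: the
#' population list, the projection list, and the drive dispersion rule
#' (per-neuron bias SD = `drive_sd_fraction` of the population mean).
#'
#' @param populations list of [population_spec()]s.
#' @param projections list of [projection()]s.
#' @param drive_sd_fraction SD of per-neuron drive as a fraction of the
#'   population mean (default 0.25).
#' @return An object of class `cpg_network`.
#' @export
network_config <- function(populations, projections,
                           drive_sd_fraction = 0.25) {
  names(populations) <- vapply(populations, `[[`, "", "name")
  cfg <- structure(list(populations = populations,
                        projections = projections,
                        drive_sd_fraction = drive_sd_fraction),
                   class = "cpg_network")
  cfg
}

#' Validate a network configuration
#'
#' Checks structural invariants without mutating the config: known population
#' names, counts and fractions in range, projection endpoints existing, and
#' sign consistency between each projection's kinetics and its presynaptic
#' population's neurotransmitter class.
#'
#' @param config a [network_config()].
#' @return character vector of violations (length 0 when valid).
#' @export
validate_network <- function(config) {
  v <- character(0)
  pops <- config$populations
  for (p in pops) {
    if (!p$name %in% POP_NAMES)
      v <- c(v, sprintf("unknown population '%s'", p$name))
    if (p$n < 1) v <- c(v, sprintf("population '%s' has n < 1", p$name))
    if (p$drive_mean < 0)
      v <- c(v, sprintf("population '%s' has negative drive", p$name))
  }
  for (pr in config$projections) {
    for (end in c(pr$pre, pr$post)) {
      if (!end %in% names(pops))
        v <- c(v, sprintf("projection endpoint '%s' does not exist", end))
    }
    cls <- unname(POP_SIGN[pr$pre])
    if (!is.na(cls)) {
      expected <- if (identical(cls, "mixed")) {
        if (pr$pre_subset == "all") NA_character_ else pr$pre_subset
      } else cls
      if (!is.na(expected) && !identical(pr$kinetics$sign, expected))
        v <- c(v, sprintf(
          "projection %s->%s is %s but presynaptic class is %s",
          pr$pre, pr$post, pr$kinetics$sign, expected))
      if (identical(cls, "mixed") && pr$pre_subset == "all")
        v <- c(v, sprintf(
          "projection %s->%s draws from a mixed population without pre_subset",
          pr$pre, pr$post))
    }
  }
  if (config$drive_sd_fraction < 0)
    v <- c(v, "drive_sd_fraction must be >= 0")
  v
}

#' Draw per-neuron drive biases for one population
#'
#' Descending/tonic drive is heterogeneous across neurons: each neuron's bias
#' is drawn from a normal distribution with the population mean and an SD of
#' `sd_fraction` (default 25%) of that mean. A zero mean yields all-zero
#' biases.
#'
#' @param pop a [population_spec()].
#' @param sd_fraction SD as a fraction of the mean.
#' @return numeric vector of length `pop$n` (pA).
#' @export
assign_drive <- function(pop, sd_fraction = 0.25) {
  if (pop$drive_mean == 0) return(rep(0, pop$n))
  stats::rnorm(pop$n, mean = pop$drive_mean,
               sd = sd_fraction * pop$drive_mean)
}

#' Realize a network configuration into neurons and synapses
#'
#' Samples the probabilistic wiring: per-neuron drive biases
#' ([assign_drive()]), an independent Bernoulli(`p_connect`) draw per ordered
#' neuron pair (autapses excluded), synapse weights from
#' `Normal(weight_mean, weight_sd)` clipped at 0, and deterministic
#' assignment of bursting mode to the first `round(bursting_fraction * n)`
#' neurons of each population (neurons within a population are exchangeable).
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param config a [network_config()]; must pass [validate_network()].
#' @return A list of class `cpg_realized` with elements `neurons`
#'   (data.frame: id, population, mode, subclass, bias), `params` (matrix of
#'   per-neuron AdEx constants), `synapses` (data.frame: pre, post, weight,
#'   kinetics_id, delay), and `kinetics` (data.frame: tau_rise, tau_decay,
#'   inhibitory).
#' @export
build_network <- function(config) {
  bad <- validate_network(config)
  if (length(bad)) stop("invalid network config:\n  ", paste(bad, collapse = "\n  "))
  pops <- config$populations
  if (!length(pops)) stop("empty network: no populations")

  n_per <- vapply(pops, `[[`, integer(1), "n")
  start <- cumsum(c(0L, n_per[-length(n_per)]))
  names(start) <- names(pops)
  n_total <- sum(n_per)

  pcols <- c("C", "gL", "EL", "DeltaT", "Vth", "tau_w", "a", "b",
             "Vreset", "t_ref", "Ee", "Ei", "Ibias")
  params <- matrix(0, n_total, length(pcols), dimnames = list(NULL, pcols))
  neurons <- data.frame(id = seq_len(n_total),
                        population = rep(names(pops), n_per),
                        mode = "tonic", subclass = "excitatory",
                        bias = 0, stringsAsFactors = FALSE)

  for (p in pops) {
    idx <- start[p$name] + seq_len(p$n)
    n_exc <- round(p$excitatory_fraction * p$n)
    n_burst <- round(p$bursting_fraction * p$n)
    subclass <- rep(c("excitatory", "inhibitory"), c(n_exc, p$n - n_exc))
    mode <- rep(c("bursting", "tonic"), c(n_burst, p$n - n_burst))
    bias <- assign_drive(p, config$drive_sd_fraction)
    neurons$subclass[idx] <- subclass
    neurons$mode[idx] <- mode
    neurons$bias[idx] <- bias
    for (j in seq_along(idx)) {
      tmpl <- if (mode[j] == "bursting") p$params_bursting else p$params_tonic
      params[idx[j], ] <- unlist(tmpl[pcols])
    }
    params[idx, "Ibias"] <- params[idx, "Ibias"] + bias
  }

  # deduplicate kinetics classes
  kin_key <- vapply(config$projections, function(pr)
    paste(pr$kinetics$tau_rise, pr$kinetics$tau_decay, pr$kinetics$sign),
    "")
  kin_ids <- match(kin_key, unique(kin_key))
  ukin <- config$projections[match(unique(kin_key), kin_key)]
  kinetics <- data.frame(
    tau_rise = vapply(ukin, function(pr) pr$kinetics$tau_rise, 0),
    tau_decay = vapply(ukin, function(pr) pr$kinetics$tau_decay, 0),
    inhibitory = vapply(ukin, function(pr)
      identical(pr$kinetics$sign, "inhibitory"), NA))

  syn <- vector("list", length(config$projections))
  for (j in seq_along(config$projections)) {
    pr <- config$projections[[j]]
    pre_pop <- pops[[pr$pre]]
    pre_idx <- start[pr$pre] + seq_len(pre_pop$n)
    if (pr$pre_subset != "all") {
      keep <- neurons$subclass[pre_idx] == pr$pre_subset
      pre_idx <- pre_idx[keep]
    }
    post_idx <- start[pr$post] + seq_len(pops[[pr$post]]$n)
    if (!length(pre_idx) || !length(post_idx) || pr$p_connect == 0) {
      syn[[j]] <- NULL
      next
    }
    pairs <- expand.grid(pre = pre_idx, post = post_idx,
                         KEEP.OUT.ATTRS = FALSE)
    if (pr$pre == pr$post) pairs <- pairs[pairs$pre != pairs$post, ]
    hit <- stats::runif(nrow(pairs)) < pr$p_connect
    pairs <- pairs[hit, , drop = FALSE]
    if (!nrow(pairs)) next
    wgt <- pmax(0, stats::rnorm(nrow(pairs), pr$weight_mean, pr$weight_sd))
    syn[[j]] <- data.frame(pre = pairs$pre, post = pairs$post, weight = wgt,
                           kinetics_id = kin_ids[j], delay = pr$delay,
                           projection = j)
  }
  syn <- do.call(rbind, syn)
  if (is.null(syn))
    syn <- data.frame(pre = integer(0), post = integer(0),
                      weight = numeric(0), kinetics_id = integer(0),
                      delay = numeric(0), projection = integer(0))

  structure(list(neurons = neurons, params = params, synapses = syn,
                 kinetics = kinetics, config = config),
            class = "cpg_realized")
}

#' Export realized connectivity as an edge list
#'
#' @param realized a [build_network()] result.
#' @return data.frame with columns `pre_id`, `post_id`, `weight_nS`,
#'   `delay_ms`, `sign`.
#' @export
realized_edges <- function(realized) {
  s <- realized$synapses
  data.frame(pre_id = s$pre, post_id = s$post, weight_nS = s$weight,
             delay_ms = s$delay,
             sign = ifelse(realized$kinetics$inhibitory[s$kinetics_id],
                           "inhibitory", "excitatory"))
}

#' Reduce a network to its isolated rhythm-generating populations
#'
#' Keeps only the flexor and extensor RG populations with their
#' within-population (recurrent) projections and descending drives; every
#' other population and all cross-population projections are removed. Used to
#' characterize the intrinsic behavior of the half-centers: the flexor RG
#' bursts rhythmically in isolation while the extensor RG fires tonically.
#' Idempotent.
#'
#' @param config a [network_config()].
#' @return the reduced `cpg_network`.
#' @export
isolate_rgs <- function(config) {
  keep_pops <- config$populations[names(config$populations) %in%
                                    c("RG_F", "RG_E")]
  keep_proj <- Filter(function(pr) pr$pre == pr$post &&
                        pr$pre %in% c("RG_F", "RG_E"),
                      config$projections)
  network_config(keep_pops, keep_proj, config$drive_sd_fraction)
}
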