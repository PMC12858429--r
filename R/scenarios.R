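#' Disease-stage configuration
#'
#' Declarative description of one time point of ALS-like degeneration:
#' per-population cell survival fractions, the scale applied to the
#' connection probability of every projection whose presynaptic population
#' is V1-derived (V1RG, Ia, RC), and the multiplier on the cholinergic
#' V0c-to-motoneuron synapse weights. Descending drives are never touched.
#'
#' The shipped stage table (see [stage_table()]) encodes: at P45 a 50% loss
#' of V1 projections with cells intact; at P63 additional V1 cell
#' dysregulation; at P112 deeper V1 loss plus motoneuron and V2a loss and
#' the V0c weight increase.
#'
#' @param stage one of `"healthy"`, `"P45"`, `"P63"`, `"P112"`.
#' @param survival named numeric vector/list of survival fractions in
#'   `[0, 1]` per population (unnamed populations survive fully).
#' @param v1_projection_scale multiplier on `p_connect` of V1-presynaptic
#'   projections (0.5 from P45 onward).
#' @param v0c_weight_scale multiplier on V0c->MNP `weight_mean` (> 1 at
#'   P112 only).
#' @return An object of class `stage_config`.
#' @export
stage_config <- function(stage, survival = list(),
                         v1_projection_scale = 1, v0c_weight_scale = 1) {
  survival <- unlist(survival)
  if (length(survival) && (any(survival < 0) || any(survival > 1)))
    stop("survival fractions must lie in [0, 1]")
  stopifnot(v1_projection_scale > 0, v0c_weight_scale > 0)
  structure(list(stage = stage, survival = survival,
                 v1_projection_scale = v1_projection_scale,
                 v0c_weight_scale = v0c_weight_scale),
            class = "stage_config")
}

#' The shipped disease-stage table
#'
#' Reads `inst/extdata/stages.yaml`, the editable per-stage table of
#' survival fractions and scales. The fractions are directionally faithful
#' defaults (V1 populations affected earliest and deepest; motoneurons and
#' V2a interneurons lost only at the late stage), not transcriptions of any
#' measured counts.
#'
#' @param stage optional stage name; if given, returns that
#'   [stage_config()], otherwise the full named list.
#' @return named list of `stage_config`s, or a single one.
#' @export
stage_table <- function(stage = NULL) {
  path <- system.file("extdata", "stages.yaml", package = "spinalcpg",
                      mustWork = TRUE)
  y <- yaml::read_yaml(path)
  tbl <- lapply(names(y), function(nm) {
    s <- y[[nm]]
    stage_config(nm,
                 survival = if (is.null(s$survival)) list() else s$survival,
                 v1_projection_scale = if (is.null(s$v1_projection_scale)) 1
                                       else s$v1_projection_scale,
                 v0c_weight_scale = if (is.null(s$v0c_weight_scale)) 1
                                    else s$v0c_weight_scale)
  })
  names(tbl) <- names(y)
  # degeneration must be monotone across stages for every named population
  ord <- intersect(c("P45", "P63", "P112"), names(tbl))
  all_pops <- unique(unlist(lapply(tbl[ord], function(s) names(s$survival))))
  for (p in all_pops) {
    sv <- vapply(tbl[ord], function(s)
      if (p %in% names(s$survival)) s$survival[[p]] else 1, 0)
    if (any(diff(sv) > 1e-12))
      stop("survival of ", p, " increases across stages in stages.yaml")
  }
  if (is.null(stage)) tbl else {
    if (!stage %in% names(tbl))
      stop("unknown stage '", stage, "'; available: ",
           paste(names(tbl), collapse = ", "))
    tbl[[stage]]
  }
}

#' Apply a disease stage to the healthy network
#'
#' Reduces each affected population's count to
#' `round(survival * n_healthy)` (which neurons die is left to the trial's
#' wiring realization, so survival holds in expectation per trial), scales
#' `p_connect` of every V1-presynaptic projection (V1RG, Ia, RC) by
#' `v1_projection_scale`, and multiplies the V0c->MNP `weight_mean` by
#' `v0c_weight_scale`. Drive means and SDs, and the tonic Ia drive, are
#' left unchanged across all time points.
#'
#' @param config the healthy [network_config()].
#' @param stage a [stage_config()] or stage name resolved via
#'   [stage_table()].
#' @return the transformed `cpg_network`.
#' @export
apply_stage <- function(config, stage) {
  if (is.character(stage)) stage <- stage_table(stage)
  for (p in names(stage$survival)) {
    if (!p %in% names(config$populations))
      stop("stage survival names unknown population '", p, "'")
    s <- stage$survival[[p]]
    if (s < 0 || s > 1) stop("survival fraction out of [0, 1] for ", p)
    config$populations[[p]]$n <-
      max(1L, as.integer(round(s * config$populations[[p]]$n)))
  }
  config$projections <- lapply(config$projections, function(pr) {
    if (pr$pre %in% V1_POPS)
      pr$p_connect <- pr$p_connect * stage$v1_projection_scale
    if (grepl("^V0c", pr$pre) && grepl("^MNP", pr$post))
      pr$weight_mean <- pr$weight_mean * stage$v0c_weight_scale
    pr
  })
  config
}

#' Intervention configuration
#'
#' Declarative description of the interventions explored on top of a disease
#' stage: strengthening the remaining V1 synapses (`stabilize_v1`,
#' modeling Esyt1-mediated presynaptic stabilization), sparing the V2a
#' and/or motoneuron populations from cell loss, full V1 cell-and-synapse
#' rescue (optionally with the late-stage V0c weight boost), and slowed
#' synaptic dynamics (rise/decay multipliers on the RC->MNP and Ia->MNP
#' inhibitory and MNP->RC excitatory connections of the selected side).
#' Stabilization and full rescue are mutually exclusive.
#'
#' @param stabilize_v1 weight multiplier on surviving V1-presynaptic
#'   projections; 1 = off; the condition matrix ships a factor of 3,
#'   tuned so stabilization approximately restores the healthy V1
#'   inhibition product across stages.
#' @param spare_v2a,spare_mn logical; restore the population counts (and any
#'   degenerated incident connection probabilities) to healthy.
#' @param rescue_v1 logical; restore V1 populations and V1 projection
#'   probabilities to healthy.
#' @param v0c_boost_with_rescue logical; apply the late-stage V0c->MNP
#'   weight multiplier together with the rescue.
#' @param slow_dynamics `"none"`, `"flexor"`, `"extensor"` or
#'   `"symmetric"`.
#' @param slow_factor multiplier on both rise and decay time constants of
#'   the targeted projections (shipped default 2).
#' @param v0c_boost_factor the V0c weight multiplier used with
#'   `v0c_boost_with_rescue`.
#' @return An object of class `intervention_config`.
#' @export
intervention_config <- function(stabilize_v1 = 1, spare_v2a = FALSE,
                                spare_mn = FALSE, rescue_v1 = FALSE,
                                v0c_boost_with_rescue = FALSE,
                                slow_dynamics = c("none", "flexor",
                                                  "extensor", "symmetric"),
                                slow_factor = 2, v0c_boost_factor = 1.5) {
  slow_dynamics <- match.arg(slow_dynamics)
  stopifnot(stabilize_v1 > 0, slow_factor > 0, v0c_boost_factor > 0)
  if (rescue_v1 && stabilize_v1 != 1)
    stop("V1 rescue and V1 stabilization are mutually exclusive")
  structure(list(stabilize_v1 = stabilize_v1, spare_v2a = spare_v2a,
                 spare_mn = spare_mn, rescue_v1 = rescue_v1,
                 v0c_boost_with_rescue = v0c_boost_with_rescue,
                 slow_dynamics = slow_dynamics, slow_factor = slow_factor,
                 v0c_boost_factor = v0c_boost_factor),
            class = "intervention_config")
}

#' Apply an intervention to a stage-transformed network
#'
#' @param config a stage-transformed [network_config()] (see
#'   [apply_stage()]).
#' @param iv an [intervention_config()].
#' @param healthy the healthy reference config used to restore spared or
#'   rescued blocks (defaults to [healthy_network()]).
#' @return the transformed `cpg_network`.
#' @export
apply_intervention <- function(config, iv, healthy = healthy_network()) {
  restore_pop <- function(cfg, pops) {
    for (p in pops) {
      cfg$populations[[p]]$n <- healthy$populations[[p]]$n
    }
    cfg
  }
  if (iv$spare_v2a) config <- restore_pop(config, c("V2a_F", "V2a_E"))
  if (iv$spare_mn) config <- restore_pop(config, c("MNP_F", "MNP_E"))
  if (iv$rescue_v1) {
    config <- restore_pop(config, intersect(V1_POPS,
                                            names(config$populations)))
    for (j in seq_along(config$projections)) {
      if (config$projections[[j]]$pre %in% V1_POPS)
        config$projections[[j]]$p_connect <-
          healthy$projections[[j]]$p_connect
    }
  }
  if (iv$v0c_boost_with_rescue) {
    config$projections <- lapply(config$projections, function(pr) {
      if (grepl("^V0c", pr$pre) && grepl("^MNP", pr$post))
        pr$weight_mean <- pr$weight_mean * iv$v0c_boost_factor
      pr
    })
  }
  if (iv$stabilize_v1 != 1) {
    config$projections <- lapply(config$projections, function(pr) {
      if (pr$pre %in% V1_POPS)
        pr$weight_mean <- pr$weight_mean * iv$stabilize_v1
      pr
    })
  }
  if (iv$slow_dynamics != "none") {
    sides <- switch(iv$slow_dynamics,
                    flexor = "F", extensor = "E", symmetric = c("F", "E"))
    config$projections <- lapply(config$projections, function(pr) {
      for (s in sides) {
        slow_target <-
          (pr$pre == paste0("RC_", s) && pr$post == paste0("MNP_", s)) ||
          (pr$pre == paste0("Ia_", s) && pr$post == paste0("MNP_", s)) ||
          (pr$pre == paste0("MNP_", s) && pr$post == paste0("RC_", s))
        if (slow_target) {
          pr$kinetics$tau_rise <- pr$kinetics$tau_rise * iv$slow_factor
          pr$kinetics$tau_decay <- pr$kinetics$tau_decay * iv$slow_factor
        }
      }
      pr
    })
  }
  config
}

#' The canonical condition matrix
#'
#' Enumerates the named disease-stage x intervention conditions studied with
#' the model: the healthy baseline, the three untreated stages, the
#' late-stage sparing combinations, V1 stabilization at every stage (alone
#' and combined with sparing), V1 cell-and-synapse rescue with and without
#' the V0c boost, and the slowed-synaptic-dynamics variants at the early
#' stage.
#'
#' @return named list of scenario descriptors, each with `name`, `stage`,
#'   `intervention` ([intervention_config()]) and `panel` (the variance-plot
#'   panel the condition corresponds to).
#' @export
condition_matrix <- function() {
  iv <- intervention_config
  defs <- list(
    list("healthy", "healthy", iv(), "baseline"),
    list("P45_no_intervention", "P45", iv(), "disease early"),
    list("P63_no_intervention", "P63", iv(), "disease mid"),
    list("P112_no_intervention", "P112", iv(), "disease late"),
    list("P112_spare_mn", "P112", iv(spare_mn = TRUE), "sparing"),
    list("P112_spare_v2a", "P112", iv(spare_v2a = TRUE), "sparing"),
    list("P112_spare_v2a_mn", "P112",
         iv(spare_v2a = TRUE, spare_mn = TRUE), "sparing"),
    list("P45_stabilized", "P45", iv(stabilize_v1 = 3.0), "stabilization"),
    list("P63_stabilized", "P63", iv(stabilize_v1 = 3.0), "stabilization"),
    list("P112_stabilized", "P112", iv(stabilize_v1 = 3.0), "stabilization"),
    list("P112_stabilized_spare_mn", "P112",
         iv(stabilize_v1 = 3.0, spare_mn = TRUE), "stabilization + sparing"),
    list("P112_stabilized_spare_v2a", "P112",
         iv(stabilize_v1 = 3.0, spare_v2a = TRUE), "stabilization + sparing"),
    list("P112_stabilized_spare_v2a_mn", "P112",
         iv(stabilize_v1 = 3.0, spare_v2a = TRUE, spare_mn = TRUE),
         "stabilization + sparing"),
    list("P112_rescue_v1", "P112", iv(rescue_v1 = TRUE), "rescue"),
    list("P112_rescue_v1_v0c_boost", "P112",
         iv(rescue_v1 = TRUE, v0c_boost_with_rescue = TRUE), "rescue"),
    list("P45_slow_dynamics", "P45", iv(slow_dynamics = "flexor"),
         "slow dynamics"),
    list("P45_slow_dynamics_stabilized", "P45",
         iv(stabilize_v1 = 3.0, slow_dynamics = "flexor"), "slow dynamics"),
    list("P45_slow_dynamics_extensor", "P45",
         iv(slow_dynamics = "extensor"), "slow dynamics variants"),
    list("P45_slow_dynamics_symmetric", "P45",
         iv(slow_dynamics = "symmetric"), "slow dynamics variants"))
  out <- lapply(defs, function(d)
    structure(list(name = d[[1]], stage = d[[2]], intervention = d[[3]],
                   panel = d[[4]]), class = "scenario_config"))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Build the network configuration for a named condition
#'
#' Resolves a condition through [condition_matrix()] and applies its stage
#' then its intervention to the healthy network.
#'
#' @param condition condition name (see `names(condition_matrix())`) or a
#'   `scenario_config`.
#' @param healthy healthy base config.
#' @return a `cpg_network`.
#' @export
build_condition <- function(condition, healthy = healthy_network()) {
  if (is.character(condition)) {
    cm <- condition_matrix()
    if (!condition %in% names(cm))
      stop("unknown condition '", condition, "'; valid conditions:\n  ",
           paste(names(cm), collapse = "\n  "))
    condition <- cm[[condition]]
  }
  cfg <- if (identical(condition$stage, "healthy")) healthy
         else apply_stage(healthy, condition$stage)
  apply_intervention(cfg, condition$intervention, healthy = healthy)
}
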