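#' Read a network configuration from a YAML file
#'
#' The file format mirrors [network_config()]: top-level
#' `drive_sd_fraction`, `neuron_defaults` (tonic/bursting AdEx templates),
#' a named `kinetics` table (tau_rise, tau_decay, sign), `populations`
#' (optionally with per-population `tonic`/`bursting` parameter overrides),
#' and `projections` referencing kinetics by name.
#'
#' @param path YAML file path.
#' @return a [network_config()] object.
#' @export
read_network_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  tonic_def <- y$neuron_defaults$tonic
  burst_def <- y$neuron_defaults$bursting
  kins <- lapply(y$kinetics, function(k)
    synapse_kinetics(k$tau_rise, k$tau_decay, k$sign))

  pops <- lapply(y$populations, function(p) {
    # [[ ]] with exact names: `$` partial matching is a trap here
    # (e.g. `bursting` would match `bursting_fraction`)
    pt <- utils::modifyList(c(tonic_def, mode = "tonic"),
                            if (is.null(p[["tonic"]])) list()
                            else p[["tonic"]])
    pb <- utils::modifyList(c(burst_def, mode = "bursting"),
                            if (is.null(p[["bursting"]])) list()
                            else p[["bursting"]])
    population_spec(
      name = p$name, n = p[["n"]],
      excitatory_fraction = if (is.null(p$excitatory_fraction)) 1
                            else p$excitatory_fraction,
      bursting_fraction = if (is.null(p$bursting_fraction)) 0
                          else p$bursting_fraction,
      drive_mean = if (is.null(p$drive_mean)) 0 else p$drive_mean,
      params_tonic = do.call(adex_params, pt),
      params_bursting = do.call(adex_params, pb))
  })

  projs <- lapply(y$projections, function(pr) {
    if (!pr$kinetics %in% names(kins))
      stop("projection ", pr$pre, "->", pr$post,
           " references unknown kinetics '", pr$kinetics, "'")
    projection(
      pre = pr$pre, post = pr$post, p_connect = pr$p_connect,
      weight_mean = pr$weight_mean, weight_sd = pr$weight_sd,
      kinetics = kins[[pr$kinetics]],
      delay = if (is.null(pr$delay)) 1 else pr$delay,
      pre_subset = if (is.null(pr$pre_subset)) "all" else pr$pre_subset)
  })

  network_config(pops, projs,
                 drive_sd_fraction = if (is.null(y$drive_sd_fraction)) 0.25
                                     else y$drive_sd_fraction)
}

#' The shipped healthy flexor-extensor CPG network
#'
#' Loads the canonical healthy network configuration distributed with the
#' package (`inst/extdata/healthy_network.yaml`): two rhythm-generating
#' half-centers (4:1 excitatory:inhibitory, 30% bursting neurons on the
#' flexor side, 10% on the extensor side) mutually inhibiting each other
#' through the V1RG and V2b relay populations, V2a excitation of the
#' motoneuron pools, reciprocal Ia inhibition, recurrent Renshaw-cell
#' inhibition, cholinergic V0c drive to motoneurons, and descending/tonic
#' drives with per-neuron SD equal to 25% of the population mean. This file
#' is the single source of truth for the healthy model; disease stages and
#' interventions are config transforms applied on top of it.
#'
#' @return a [network_config()] object.
#' @export
healthy_network <- function() {
  path <- system.file("extdata", "healthy_network.yaml",
                      package = "spinalcpg", mustWork = TRUE)
  read_network_yaml(path)
}
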