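#' Experiment specification
#'
#' @param conditions character vector of condition names (see
#'   [condition_matrix()]); `"all"` expands to the full matrix.
#' @param seeds trial seed list (shared across conditions).
#' @param duration_ms,dt_ms simulation length and step.
#' @param out_dir output directory (created if missing).
#' @param write_spikes logical; write one spike table per trial.
#' @param plots logical; write variance plots and example trace panels.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(conditions = "healthy", seeds = 1:25,
                            duration_ms = 10000, dt_ms = 0.1,
                            out_dir = "spinalcpg_out",
                            write_spikes = FALSE, plots = FALSE) {
  if (identical(conditions, "all")) conditions <- names(condition_matrix())
  unknown <- setdiff(conditions, names(condition_matrix()))
  if (length(unknown))
    stop("unknown condition(s): ", paste(unknown, collapse = ", "),
         "\nvalid conditions:\n  ",
         paste(names(condition_matrix()), collapse = "\n  "))
  structure(list(conditions = conditions, seeds = seeds,
                 duration_ms = duration_ms, dt_ms = dt_ms,
                 out_dir = out_dir, write_spikes = write_spikes,
                 plots = plots),
            class = "experiment_spec")
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Run an experiment end-to-end
#'
#' For every condition: run the seed battery, write the per-trial metric
#' table (tab-separated), optionally the per-trial spike tables, the
#' flexor-vs-extensor statistics, the variance-plot data (median, quartiles,
#' 1.5 IQR whiskers per metric and side), and optionally figures. A
#' `manifest.json` records the package version, seed list, spec and config
#' hash so any output can be regenerated from the manifest alone. Failures
#' of individual trials are recorded in the manifest and the battery
#' continues.
#'
#' @param spec an [experiment_spec()].
#' @param healthy healthy base network config.
#' @return (invisibly) list with the batteries and the manifest.
#' @export
run_experiment <- function(spec, healthy = healthy_network()) {
  dir.create(spec$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "spinalcpg",
                   version = as.character(utils::packageVersion("spinalcpg")),
                   seeds = spec$seeds, duration_ms = spec$duration_ms,
                   dt_ms = spec$dt_ms, conditions = spec$conditions,
                   config_hash = config_hash(unclass_deep(healthy)),
                   failures = list(), files = character(0))
  batteries <- list()
  for (cond in spec$conditions) {
    config <- build_condition(cond, healthy = healthy)
    rows <- list()
    for (sd in spec$seeds) {
      m <- tryCatch({
        sim <- simulate_network(config, duration_ms = spec$duration_ms,
                                dt_ms = spec$dt_ms, seed = sd)
        if (spec$write_spikes) {
          sp_path <- file.path(spec$out_dir,
                               sprintf("spikes_%s_seed%03d.tsv", cond, sd))
          write_spikes(sim, sp_path)
          manifest$files <- c(manifest$files, basename(sp_path))
        }
        trial_metrics(sim)
      }, error = function(e) {
        manifest$failures[[length(manifest$failures) + 1L]] <<-
          list(condition = cond, seed = sd, error = conditionMessage(e))
        NULL
      })
      if (!is.null(m))
        rows[[length(rows) + 1L]] <- cbind(condition = cond, seed = sd, m,
                                           stringsAsFactors = FALSE)
    }
    bat <- do.call(rbind, rows)
    attr(bat, "seeds") <- spec$seeds
    class(bat) <- c("trial_battery", class(bat))
    batteries[[cond]] <- bat

    mt_path <- file.path(spec$out_dir, sprintf("metrics_%s.tsv", cond))
    utils::write.table(bat, mt_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$files <- c(manifest$files, basename(mt_path))

    vp_path <- file.path(spec$out_dir, sprintf("variance_%s.tsv", cond))
    utils::write.table(variance_plot_data(bat), vp_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$files <- c(manifest$files, basename(vp_path))

    if (spec$plots) {
      pl_path <- file.path(spec$out_dir, sprintf("plots_%s.pdf", cond))
      plot_condition(bat, file = pl_path)
      manifest$files <- c(manifest$files, basename(pl_path))
    }
  }
  # flexor-vs-extensor stats per condition, all metrics
  stats_rows <- list()
  for (cond in names(batteries)) {
    for (metric in c("avg_max_rate_hz", "freq_hz", "burst_ms", "phase_deg")) {
      cr <- flexor_vs_extensor(batteries[[cond]], metric)
      stats_rows[[length(stats_rows) + 1L]] <-
        data.frame(condition = cond, metric = metric,
                   p_value = unname(cr$p_values), stars = unname(cr$stars),
                   median_flexor = cr$medians[["flexor"]],
                   median_extensor = cr$medians[["extensor"]],
                   n = cr$n, stringsAsFactors = FALSE)
    }
  }
  st_path <- file.path(spec$out_dir, "stats_flexor_vs_extensor.tsv")
  utils::write.table(do.call(rbind, stats_rows), st_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$files <- c(manifest$files, basename(st_path))

  jsonlite::write_json(manifest, file.path(spec$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(batteries = batteries, manifest = manifest))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Variance-plot summary data
#'
#' Median, first/third quartiles and whiskers at 1.5 times the
#' interquartile range per metric and side, after per-metric 3-SD outlier
#' exclusion; the convention used by the condition-comparison figures.
#'
#' @param battery a [run_battery()] result.
#' @return data.frame with `metric`, `side`, `n`, `median`, `q1`, `q3`,
#'   `whisker_lo`, `whisker_hi`, `n_excluded`.
#' @export
variance_plot_data <- function(battery) {
  rows <- list()
  for (metric in c("avg_max_rate_hz", "freq_hz", "burst_ms", "phase_deg")) {
    for (side in c("F", "E")) {
      k <- battery_kept(battery, metric, side)
      v <- k$values[!is.na(k$values)]
      if (!length(v)) {
        rows[[length(rows) + 1L]] <-
          data.frame(metric = metric, side = side, n = 0L,
                     median = NA, q1 = NA, q3 = NA,
                     whisker_lo = NA, whisker_hi = NA,
                     n_excluded = length(k$excluded_seeds))
        next
      }
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, side = side, n = length(v),
        median = q[2], q1 = q[1], q3 = q[3],
        whisker_lo = max(min(v), q[1] - 1.5 * iqr),
        whisker_hi = min(max(v), q[3] + 1.5 * iqr),
        n_excluded = length(k$excluded_seeds))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Variance plots and example rate traces for a condition
#'
#' Box-style variance plots (median, quartiles, whiskers at 1.5 IQR) of the
#' four metrics by side, with the 100 Hz reference line on the firing-rate
#' panel, plus (optionally) flexor/extensor rate-trace panels for an example
#' seed. Trials with missing metrics are omitted with a printed count.
#'
#' @param battery a [run_battery()] result.
#' @param file optional PDF path; if `NULL` the ggplot object is returned.
#' @param example_sim optional `cpg_sim` for the trace panel.
#' @return the ggplot object (invisibly if written to file).
#' @export
plot_condition <- function(battery, file = NULL, example_sim = NULL) {
  df <- as.data.frame(battery)
  long <- do.call(rbind, lapply(
    c("avg_max_rate_hz", "freq_hz", "burst_ms", "phase_deg"),
    function(m) data.frame(metric = m, side = df$side, value = df[[m]])))
  n_missing <- sum(is.na(long$value))
  if (n_missing) message(n_missing, " missing metric value(s) omitted")
  long <- long[!is.na(long$value), , drop = FALSE]
  if (!nrow(long)) {
    warning("empty metric table; nothing to plot")
    return(invisible(NULL))
  }
  ref <- data.frame(metric = "avg_max_rate_hz", y = 100)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = side, y = value)) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.shape = 1) +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = y),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = df$condition[1], x = NULL, y = NULL) +
    ggplot2::theme_bw()
  if (!is.null(example_sim)) {
    tr_f <- smoothed_rate(example_sim, "MNP_F")
    tr_e <- smoothed_rate(example_sim, "MNP_E")
    traces <- rbind(
      data.frame(t = tr_f$t, rate = tr_f$rate, side = "flexor"),
      data.frame(t = tr_e$t, rate = tr_e$rate, side = "extensor"))
    keep <- seq(1, nrow(traces), by = 10)  # thin for plotting
    ptr <- ggplot2::ggplot(traces[keep, ],
                           ggplot2::aes(t, rate, colour = side)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 100, linetype = "dotted",
                          colour = "grey40") +
      ggplot2::labs(x = "time (ms)", y = "rate (Hz)") +
      ggplot2::theme_bw()
    if (!is.null(file)) {
      grDevices::pdf(file, width = 8, height = 6)
      print(p); print(ptr)
      grDevices::dev.off()
      return(invisible(p))
    }
    return(list(variance = p, traces = ptr))
  }
  if (!is.null(file)) {
    grDevices::pdf(file, width = 8, height = 6)
    print(p)
    grDevices::dev.off()
    return(invisible(p))
  }
  p
}
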