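#' Run a multi-seed trial battery for one condition
#'
#' One wiring realization + simulation + metrics pass per seed, all fully
#' determined by the seed. The same ordered seed list must be used for every
#' condition entering a comparison. Trials whose metrics cannot be computed
#' (e.g. no rhythm peaks) are kept with `NA`s and flagged, never silently
#' dropped.
#'
#' @param condition condition name (see [condition_matrix()]) or a
#'   `cpg_network` config.
#' @param seeds integer vector of trial seeds (default `1:25`).
#' @param duration_ms,dt_ms simulation length and step.
#' @param healthy healthy base config used to resolve named conditions.
#' @param label battery label (defaults to the condition name).
#' @return An object of class `trial_battery`: data.frame with columns
#'   `condition`, `seed`, `side`, the four metrics, `n_intervals`,
#'   `missing_flags`; attribute `seeds` holds the seed list.
#' @export
run_battery <- function(condition, seeds = 1:25, duration_ms = 10000,
                        dt_ms = 0.1, healthy = healthy_network(),
                        label = NULL) {
  if (is.character(condition)) {
    if (is.null(label)) label <- condition
    config <- build_condition(condition, healthy = healthy)
  } else {
    config <- condition
    if (is.null(label)) label <- "custom"
  }
  rows <- lapply(seeds, function(sd) {
    sim <- simulate_network(config, duration_ms = duration_ms,
                            dt_ms = dt_ms, seed = sd)
    m <- trial_metrics(sim)
    cbind(condition = label, seed = sd, m, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seeds") <- seeds
  class(out) <- c("trial_battery", class(out))
  out
}

#' Three-standard-deviation outlier exclusion
#'
#' Removes values farther than 3 SDs from the mean, with mean and SD taken
#' over the full set in a single pass (no re-iteration). A zero-SD set
#' excludes nothing; `NA`s are passed through as neither kept nor excluded.
#'
#' @param values numeric vector (>= 3 non-missing values recommended).
#' @param n_sd exclusion threshold in SDs (default 3).
#' @return list with `kept` (values), `kept_idx`, `excluded_idx`.
#' @export
exclude_outliers <- function(values, n_sd = 3) {
  ok <- !is.na(values)
  m <- mean(values[ok])
  s <- stats::sd(values[ok])
  out <- ok & !is.na(values) & (if (is.na(s) || s == 0) FALSE
                                else abs(values - m) > n_sd * s)
  out[is.na(out)] <- FALSE
  list(kept = values[ok & !out],
       kept_idx = which(ok & !out),
       excluded_idx = which(out))
}

# per-metric outlier exclusion within one battery and side
battery_kept <- function(battery, metric, side) {
  v <- battery[[metric]][battery$side == side]
  sd_v <- battery$seed[battery$side == side]
  ex <- exclude_outliers(v)
  list(values = ex$kept, seeds = sd_v[ex$kept_idx],
       excluded_seeds = sd_v[ex$excluded_idx])
}

#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Two-sided paired signed-rank test. Zero differences are ranked together
#' with the rest and then dropped from the statistic (Pratt's method), which
#' keeps the test well defined under discrete ties; the p-value uses the
#' normal approximation with tie/zero-corrected variance and continuity
#' correction. All-zero differences return p = 1 ("ns" by convention).
#'
#' @param x,y paired numeric vectors.
#' @return list with `statistic` (W+, Pratt), `p_value`, `n_nonzero`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n == 0 || all(d == 0))
    return(list(statistic = NA_real_, p_value = 1, n_nonzero = sum(d != 0)))
  r <- rank(abs(d))
  wplus <- sum(r[d > 0])
  n0 <- sum(d == 0)
  # Pratt: zeros ranked then removed; moments follow Pratt (1959)
  mu <- n * (n + 1) / 4 - n0 * (n0 + 1) / 4
  ties <- table(r[d != 0])
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    n0 * (n0 + 1) * (2 * n0 + 1) / 24 -
    sum(ties^3 - ties) / 48
  if (sigma2 <= 0)
    return(list(statistic = wplus, p_value = 1, n_nonzero = n - n0))
  z <- (wplus - mu - sign(wplus - mu) * 0.5) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  list(statistic = wplus, p_value = min(1, p), n_nonzero = n - n0)
}

#' Compare flexor versus extensor within one battery
#'
#' Pairs the per-seed flexor and extensor values of one metric (after
#' per-metric 3-SD outlier exclusion applied to both sides; a seed excluded
#' on either side is dropped from the pairing) and applies the two-sided
#' Wilcoxon signed-rank test with the printed star mapping.
#'
#' @param battery a [run_battery()] result.
#' @param metric one of `"avg_max_rate_hz"`, `"freq_hz"`, `"burst_ms"`,
#'   `"phase_deg"`.
#' @return An object of class `comparison_result` with `test`, `groups`,
#'   `p_values`, `stars`, `medians`, `n`.
#' @export
flexor_vs_extensor <- function(battery, metric = "avg_max_rate_hz") {
  f <- battery_kept(battery, metric, "F")
  e <- battery_kept(battery, metric, "E")
  seeds <- intersect(f$seeds, e$seeds)
  xf <- f$values[match(seeds, f$seeds)]
  xe <- e$values[match(seeds, e$seeds)]
  keep <- !is.na(xf) & !is.na(xe)
  w <- wilcoxon_signed_rank(xf[keep], xe[keep])
  structure(list(test = "wilcoxon", metric = metric,
                 groups = c("flexor", "extensor"),
                 p_values = c("flexor vs extensor" = w$p_value),
                 stars = c("flexor vs extensor" = p_stars(w$p_value)),
                 medians = c(flexor = stats::median(xf[keep]),
                             extensor = stats::median(xe[keep])),
                 n = sum(keep)),
            class = "comparison_result")
}

#' Dunn's post-hoc test
#'
#' Pairwise z-tests on pooled mean ranks with the tie-corrected
#' Kruskal-Wallis variance, as used after a significant omnibus H-test. No
#' multiplicity adjustment is applied by default (each contrast reports its
#' own two-sided p); Holm adjustment is available.
#'
#' @param values numeric vector.
#' @param groups factor/character vector of group labels.
#' @param control optional control group label; if given only
#'   control-vs-other contrasts are returned, otherwise all pairs.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return data.frame with `contrast`, `z`, `p_value`.
#' @export
dunn_test <- function(values, groups, control = NULL, p_adjust = "none") {
  ok <- !is.na(values)
  values <- values[ok]
  groups <- as.character(groups)[ok]
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr
  labs <- names(rbar)
  pairs <- if (is.null(control)) utils::combn(labs, 2, simplify = FALSE)
           else lapply(setdiff(labs, control), function(g) c(control, g))
  res <- lapply(pairs, function(p) {
    z <- (rbar[[p[1]]] - rbar[[p[2]]]) /
      sqrt(v0 * (1 / ns[[p[1]]] + 1 / ns[[p[2]]]))
    data.frame(contrast = paste(p[1], "vs", p[2]), z = z,
               p_value = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_value <- stats::p.adjust(res$p_value, method = p_adjust)
  rownames(res) <- NULL
  res
}

#' Compare one metric across condition batteries
#'
#' Kruskal-Wallis omnibus H-test over the kept (3-SD filtered) per-trial
#' values of the chosen metric and side, followed by Dunn's post-hoc
#' contrasts of every condition against the control (the first battery by
#' default). Batteries must share the same seed list. Groups with fewer
#' than 2 kept values are dropped from the omnibus with a warning.
#'
#' @param batteries list of [run_battery()] results; the first is the
#'   control unless `control` names another.
#' @param metric metric column.
#' @param side `"F"` or `"E"`.
#' @param control control condition label.
#' @return An object of class `comparison_result` with the omnibus
#'   (`H`, `p_omnibus`) and per-contrast `p_values` and `stars`.
#' @export
across_conditions <- function(batteries, metric = "avg_max_rate_hz",
                              side = "F", control = NULL) {
  seed_sets <- lapply(batteries, attr, "seeds")
  for (s in seed_sets[-1]) {
    if (!identical(s, seed_sets[[1]]))
      stop("batteries use different seed sets; comparisons require the ",
           "same ordered seed list for every condition")
  }
  kept <- lapply(batteries, battery_kept, metric = metric, side = side)
  labs <- vapply(batteries, function(b) b$condition[1], "")
  sizes <- vapply(kept, function(k) sum(!is.na(k$values)), 0L)
  drop <- sizes < 2
  if (any(drop)) {
    warning("dropping group(s) with < 2 kept values from the omnibus: ",
            paste(labs[drop], collapse = ", "))
    kept <- kept[!drop]
    labs <- labs[!drop]
  }
  if (length(kept) < 2) stop("need at least 2 groups with kept values")
  values <- unlist(lapply(kept, `[[`, "values"))
  groups <- rep(labs, vapply(kept, function(k) length(k$values), 0L))
  kw <- stats::kruskal.test(values, factor(groups))
  if (is.null(control)) control <- labs[1]
  dn <- dunn_test(values, groups, control = control)
  p <- stats::setNames(dn$p_value, dn$contrast)
  structure(list(test = "kruskal_dunn", metric = metric, side = side,
                 groups = labs, H = unname(kw$statistic),
                 p_omnibus = kw$p.value,
                 p_values = p, stars = p_stars(p),
                 medians = vapply(kept, function(k)
                   stats::median(k$values, na.rm = TRUE), 0)),
            class = "comparison_result")
}

#' Significance star labels
#'
#' `p <= 0.001`: `***`; `0.001 < p <= 0.01`: `**`; `0.01 < p <= 0.05`: `*`;
#' `p > 0.05`: `ns`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return character vector of labels.
#' @export
p_stars <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  ifelse(is.na(p), "ns",
    ifelse(p <= 0.001, "***",
      ifelse(p <= 0.01, "**",
        ifelse(p <= 0.05, "*", "ns"))))
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(x$test, "on", x$metric,
      if (!is.null(x$side)) paste0("(side ", x$side, ")"), "\n")
  if (!is.null(x$p_omnibus))
    cat("  omnibus H =", format(x$H, digits = 4),
        " p =", format(x$p_omnibus, digits = 3), "\n")
  for (i in seq_along(x$p_values))
    cat(sprintf("  %-45s p = %-10.3g %s\n", names(x$p_values)[i],
                x$p_values[i], x$stars[i]))
  invisible(x)
}
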