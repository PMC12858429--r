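#' Gaussian-smoothed, rescaled population rate trace
#'
#' Pools all spikes of one population, convolves them with a Gaussian window
#' (SD `window` ms, truncated at 4 SD; no edge reflection, kernel mass is
#' simply cut at the record boundaries) on the simulation time grid, and
#' rescales the whole trace so its maximum equals the population's maximum
#' instantaneous firing rate. The instantaneous rate is computed per neuron
#' as `1000 / min(ISI)` Hz and maximized over neurons (a pooled-ISI variant
#' is available via `instantaneous`); e.g. a raw convolved peak of 50 with a
#' maximum instantaneous rate of 100 Hz multiplies every sample by 2. If no
#' neuron has two spikes the rescaling is skipped and the unscaled kernel
#' density (spikes/s) is returned.
#'
#' @param spikes spike data.frame (`population`, `neuron_id`, `time_ms`) or a
#'   `cpg_sim`.
#' @param population population label to pool.
#' @param duration_ms record length (taken from the `cpg_sim` if given).
#' @param dt_ms trace grid step (the simulation dt).
#' @param window Gaussian SD (ms), default 20.
#' @param instantaneous `"per_neuron"` (default) or `"pooled"`: ISI set used
#'   for the maximum instantaneous rate.
#' @param settle_ms initial transient to discard (ms): spikes and trace
#'   before this time are dropped before smoothing and rescaling, so the
#'   onset volley of a simulation (all neurons start from rest with no
#'   adaptation) does not set the trace maximum. Default 0.
#' @return An object of class `rate_trace`: list with `population`, `t`
#'   (ms), `rate` (Hz), `max_inst_rate`, `rescale_factor`, `n_spikes`. With
#'   zero spikes an empty trace is returned with a warning.
#' @export
smoothed_rate <- function(spikes, population, duration_ms = NULL,
                          dt_ms = 0.1, window = 20,
                          instantaneous = c("per_neuron", "pooled"),
                          settle_ms = 0) {
  instantaneous <- match.arg(instantaneous)
  if (inherits(spikes, "cpg_sim")) {
    duration_ms <- spikes$duration_ms
    dt_ms <- spikes$dt_ms
    spikes <- spikes$spikes
  }
  if (is.null(duration_ms)) duration_ms <- max(spikes$time_ms)
  sp <- spikes[spikes$population == population &
                 spikes$time_ms > settle_ms, , drop = FALSE]
  sp$time_ms <- sp$time_ms - settle_ms
  duration_ms <- duration_ms - settle_ms
  tgrid <- seq(dt_ms, duration_ms, by = dt_ms) + settle_ms
  if (!nrow(sp)) {
    warning("no spikes in population ", population, "; empty rate trace")
    return(structure(list(population = population, t = tgrid,
                          rate = rep(0, length(tgrid)),
                          max_inst_rate = NA_real_, rescale_factor = NA_real_,
                          n_spikes = 0L, dt_ms = dt_ms),
                     class = "rate_trace"))
  }

  n_bins <- length(tgrid)
  counts <- tabulate(pmin(n_bins, pmax(1L, as.integer(ceiling(
    sp$time_ms / dt_ms)))), nbins = n_bins)

  half <- ceiling(4 * window / dt_ms)
  kt <- seq(-half, half) * dt_ms
  kernel <- exp(-0.5 * (kt / window)^2)
  kernel <- kernel / (sum(kernel) * dt_ms / 1000)  # density in spikes/s
  full <- stats::convolve(counts, rev(kernel), type = "open")
  raw <- full[(half + 1):(half + n_bins)]
  raw[raw < 0] <- 0  # FFT round-off

  max_inst <- max_instantaneous_rate(sp, instantaneous)
  if (is.na(max_inst) || max(raw) == 0) {
    factor <- NA_real_
    rate <- raw
  } else {
    factor <- max_inst / max(raw)
    rate <- raw * factor
  }
  structure(list(population = population, t = tgrid, rate = rate,
                 max_inst_rate = max_inst, rescale_factor = factor,
                 n_spikes = nrow(sp), dt_ms = dt_ms),
            class = "rate_trace")
}

max_instantaneous_rate <- function(sp, instantaneous = "per_neuron") {
  if (instantaneous == "pooled") {
    tt <- sort(sp$time_ms)
    if (length(tt) < 2) return(NA_real_)
    isi <- min(diff(tt))
    if (isi <= 0) return(NA_real_)
    return(1000 / isi)
  }
  isis <- vapply(split(sp$time_ms, sp$neuron_id), function(tt) {
    if (length(tt) < 2) return(NA_real_)
    min(diff(sort(tt)))
  }, 0)
  isis <- isis[!is.na(isis) & isis > 0]
  if (!length(isis)) return(NA_real_)
  1000 / min(isis)
}

#' Detect rhythm peaks in a rate trace
#'
#' Local maxima filtered by the rhythm-analysis settings: minimum height
#' `min_height_fraction` (default 0.4) of the trace maximum, minimum
#' pairwise distance `min_distance` (the higher of two
#' close candidates wins), and minimum topographic prominence `prominence`
#' (default 0.1, measured on the max-normalized trace).
#'
#' @param trace a [smoothed_rate()] result, or a list/data.frame with `t`
#'   and `rate`.
#' @param min_height_fraction minimum peak height as a fraction of the trace
#'   maximum.
#' @param min_distance minimum distance between returned peaks (ms). The
#'   default 250 ms sits above the burst-width scale (so a double-humped
#'   burst is counted once) and below the shortest locomotor cycle the
#'   model produces (333 ms at 3 Hz), resolving rhythms up to 4 Hz.
#' @param prominence minimum prominence on the normalized (max = 1) trace.
#' @return An object of class `peak_set`: `times` (ms), `heights` (trace
#'   units), `settings`.
#' @export
detect_peaks <- function(trace, min_height_fraction = 0.4,
                         min_distance = 250, prominence = 0.1) {
  x <- trace$rate
  t <- trace$t
  out <- structure(list(times = numeric(0), heights = numeric(0),
                        settings = list(min_height_fraction = min_height_fraction,
                                        min_distance = min_distance,
                                        prominence = prominence)),
                   class = "peak_set")
  if (length(x) < 3 || max(x) <= 0) return(out)

  cand <- local_maxima(x)
  if (!length(cand)) return(out)
  xn <- x / max(x)
  keep <- xn[cand] >= min_height_fraction &
    peak_prominences(xn, cand) >= prominence
  cand <- cand[keep]
  if (!length(cand)) return(out)

  # distance rule: higher peaks win, scanning in decreasing height order
  ord <- cand[order(-x[cand], cand)]
  selected <- integer(0)
  for (i in ord) {
    if (!length(selected) || all(abs(t[i] - t[selected]) >= min_distance))
      selected <- c(selected, i)
  }
  selected <- sort(selected)
  out$times <- t[selected]
  out$heights <- x[selected]
  out
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  # strictly rising into the point, falling (possibly across a flat top) out
  idx <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[j]) j <- j + 1L
      if (j < n && x[j + 1] < x[j]) {
        idx <- c(idx, as.integer(floor((i + j) / 2)))
        i <- j
      }
    }
    i <- i + 1L
  }
  idx
}

peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    # walk left to the first strictly higher sample (or the edge)
    lmin <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) {
      if (x[i] < lmin) lmin <- x[i]
      i <- i - 1L
    }
    rmin <- h
    i <- p + 1L
    while (i <= length(x) && x[i] <= h) {
      if (x[i] < rmin) rmin <- x[i]
      i <- i + 1L
    }
    h - max(lmin, rmin)
  }, 0)
}

#' Oscillation frequency from detected peaks
#'
#' Period is the mean of successive peak-time differences; frequency is its
#' reciprocal converted to Hz.
#'
#' @param peaks a [detect_peaks()] result (or list with `times` in ms).
#' @return list with `period_ms`, `freq_hz`, `n_intervals`; `NA`s (with
#'   `n_intervals = 0`) when fewer than 2 peaks are available.
#' @export
peak_frequency <- function(peaks) {
  tt <- peaks$times
  if (length(tt) < 2)
    return(list(period_ms = NA_real_, freq_hz = NA_real_, n_intervals = 0L))
  d <- diff(tt)
  period <- sum(d) / length(d)
  list(period_ms = period, freq_hz = 1000 / period,
       n_intervals = length(d))
}

#' Burst segmentation from flexor/extensor trace crossings
#'
#' Flexor and extensor bursts are delimited by the crossings of the two
#' population rate traces: a flexor burst is an interval where the flexor
#' trace exceeds the extensor trace, and vice versa. Crossing times are
#' localized by linear interpolation between grid points; partial bursts at
#' the record edges are discarded.
#'
#' @param flexor,extensor [smoothed_rate()] traces on the same time grid.
#' @return list with `crossings` (ms), `segments` (data.frame: side, start,
#'   end, duration, midpoint) and `mean_duration` (named vector, ms; `NA`
#'   when a side has no complete burst). With no crossings, empty segments.
#' @export
burst_segments <- function(flexor, extensor) {
  if (length(flexor$t) != length(extensor$t) ||
      any(flexor$t != extensor$t))
    stop("flexor and extensor traces must share the same time grid")
  t <- flexor$t
  d <- flexor$rate - extensor$rate
  s <- sign(d)
  flip <- which(s[-1] * s[-length(s)] < 0)
  # linear interpolation of the zero crossing within [i, i+1]
  crossings <- t[flip] + (t[flip + 1] - t[flip]) * d[flip] / (d[flip] - d[flip + 1])

  empty <- list(crossings = crossings,
                segments = data.frame(side = character(0), start = numeric(0),
                                      end = numeric(0), duration = numeric(0),
                                      midpoint = numeric(0)),
                mean_duration = c(F = NA_real_, E = NA_real_))
  if (length(crossings) < 2) return(empty)

  start <- crossings[-length(crossings)]
  end <- crossings[-1]
  mid_idx <- pmin(length(t), pmax(1L, round(((start + end) / 2 - t[1]) /
                                              flexor$dt_ms) + 1L))
  side <- ifelse(d[mid_idx] > 0, "F", ifelse(d[mid_idx] < 0, "E", NA))
  seg <- data.frame(side = side, start = start, end = end,
                    duration = end - start, midpoint = (start + end) / 2,
                    stringsAsFactors = FALSE)
  seg <- seg[!is.na(seg$side) & seg$duration > 0, , drop = FALSE]
  mean_dur <- c(F = mean(seg$duration[seg$side == "F"]),
                E = mean(seg$duration[seg$side == "E"]))
  list(crossings = crossings, segments = seg, mean_duration = mean_dur)
}

#' Flexor-extensor phase difference
#'
#' For each pair of successive flexor burst midpoints (m_F1, m_F2) with an
#' extensor burst midpoint m_E between them, the cycle phase is
#' `360 * (m_E - m_F1) / (m_F2 - m_F1)` degrees, folded into `[0, 180]`
#' (values above 180 map to `360 - x`). The trial value is the mean over
#' cycles.
#'
#' The formula presumes one flexor and one extensor burst per cycle.
#' Crossing-based segmentation can emit spurious sub-bursts (baseline
#' pop-ups, pre-burst ramps), so when `flexor_peaks` is supplied the flexor
#' midpoints are anchored on the segments that contain a detected rhythm
#' peak, and the extensor midpoint of a cycle is taken between the
#' crossings that bound the inter-burst interval (an extensor segment must
#' exist there). Without `flexor_peaks`, all flexor segments are used and
#' the first intervening extensor midpoint is taken.
#'
#' @param bursts a [burst_segments()] result, or a data.frame of segments.
#' @param flexor_peaks optional [detect_peaks()] result for the flexor
#'   trace, used to anchor genuine flexor bursts.
#' @return list with `phase_deg` (mean, `NA` when fewer than 2 flexor bursts
#'   with an intervening extensor burst exist) and `per_cycle` (vector).
#' @export
phase_difference <- function(bursts, flexor_peaks = NULL) {
  seg <- if (is.data.frame(bursts)) bursts else bursts$segments
  fseg <- seg[seg$side == "F", , drop = FALSE]
  eseg <- seg[seg$side == "E", , drop = FALSE]
  if (!is.null(flexor_peaks) && length(flexor_peaks$times)) {
    contains_peak <- vapply(seq_len(nrow(fseg)), function(i)
      any(flexor_peaks$times >= fseg$start[i] &
            flexor_peaks$times <= fseg$end[i]), NA)
    if (any(contains_peak)) fseg <- fseg[contains_peak, , drop = FALSE]
  }
  mf <- fseg$midpoint
  if (length(mf) < 2 || !nrow(eseg))
    return(list(phase_deg = NA_real_, per_cycle = numeric(0)))
  per_cycle <- numeric(0)
  anchored <- !is.null(flexor_peaks)
  for (i in seq_len(length(mf) - 1)) {
    inside <- eseg$midpoint > mf[i] & eseg$midpoint < mf[i + 1]
    if (!any(inside)) next
    me <- if (anchored) {
      # the extensor phase spans the crossings bounding the inter-burst
      # interval; its midpoint is taken between those crossings
      (fseg$end[i] + fseg$start[i + 1]) / 2
    } else {
      eseg$midpoint[inside][1]
    }
    ph <- 360 * (me - mf[i]) / (mf[i + 1] - mf[i])
    if (ph > 180) ph <- 360 - ph
    per_cycle <- c(per_cycle, ph)
  }
  if (!length(per_cycle))
    return(list(phase_deg = NA_real_, per_cycle = numeric(0)))
  list(phase_deg = mean(per_cycle), per_cycle = per_cycle)
}

#' Average maximum firing rate of a trace
#'
#' Mean height of the detected rhythm peaks of the (rescaled) rate trace;
#' with `peak_source = "local_maxima"` all local maxima of the trace are
#' averaged instead.
#'
#' @param trace a [smoothed_rate()] trace.
#' @param peaks optional precomputed [detect_peaks()] result.
#' @param peak_source `"detected"` (default) or `"local_maxima"`.
#' @return mean peak rate (Hz); `NA` if no peaks.
#' @export
avg_max_rate <- function(trace, peaks = NULL,
                         peak_source = c("detected", "local_maxima")) {
  peak_source <- match.arg(peak_source)
  if (peak_source == "local_maxima") {
    idx <- local_maxima(trace$rate)
    if (!length(idx)) return(NA_real_)
    return(mean(trace$rate[idx]))
  }
  if (is.null(peaks)) peaks <- detect_peaks(trace)
  if (!length(peaks$heights)) return(NA_real_)
  mean(peaks$heights)
}

#' Per-trial outcome metrics for the motoneuron output
#'
#' Computes the four outcome measures of one simulation: per side (flexor,
#' extensor) the average maximum firing rate and oscillation frequency of
#' the motoneuron population, the mean burst duration from trace crossings,
#' and the shared flexor-extensor phase difference.
#'
#' @param sim a `cpg_sim` (or spike data.frame with `duration_ms`/`dt_ms`
#'   supplied).
#' @param flexor_pop,extensor_pop population labels of the two output pools.
#' @param window Gaussian smoothing SD (ms).
#' @param settle_ms initial transient discarded before all metrics (ms).
#' @param duration_ms,dt_ms needed only when `sim` is a bare data.frame.
#' @return data.frame with one row per side: `side`, `avg_max_rate_hz`,
#'   `freq_hz`, `burst_ms`, `phase_deg`, `n_intervals`, `missing_flags`.
#' @export
trial_metrics <- function(sim, flexor_pop = "MNP_F", extensor_pop = "MNP_E",
                          window = 20, settle_ms = 1000, duration_ms = NULL,
                          dt_ms = 0.1) {
  tr_f <- smoothed_rate(sim, flexor_pop, duration_ms, dt_ms, window,
                        settle_ms = settle_ms)
  tr_e <- smoothed_rate(sim, extensor_pop, duration_ms, dt_ms, window,
                        settle_ms = settle_ms)
  pk_f <- detect_peaks(tr_f)
  pk_e <- detect_peaks(tr_e)
  fr_f <- peak_frequency(pk_f)
  fr_e <- peak_frequency(pk_e)
  bursts <- burst_segments(tr_f, tr_e)
  phase <- phase_difference(bursts, flexor_peaks = pk_f)

  flags <- function(rate, freq, burst) {
    miss <- c(if (is.na(rate)) "rate", if (is.na(freq)) "freq",
              if (is.na(burst)) "burst", if (is.na(phase$phase_deg)) "phase")
    if (length(miss)) paste(miss, collapse = ",") else ""
  }
  rate_f <- avg_max_rate(tr_f, pk_f)
  rate_e <- avg_max_rate(tr_e, pk_e)
  data.frame(
    side = c("F", "E"),
    avg_max_rate_hz = c(rate_f, rate_e),
    freq_hz = c(fr_f$freq_hz, fr_e$freq_hz),
    burst_ms = c(bursts$mean_duration[["F"]], bursts$mean_duration[["E"]]),
    phase_deg = phase$phase_deg,
    n_intervals = c(fr_f$n_intervals, fr_e$n_intervals),
    missing_flags = c(flags(rate_f, fr_f$freq_hz, bursts$mean_duration[["F"]]),
                      flags(rate_e, fr_e$freq_hz, bursts$mean_duration[["E"]])),
    stringsAsFactors = FALSE)
}
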