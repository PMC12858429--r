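test_that("rate rescaling pins the trace maximum to the instantaneous rate", {
  # two neurons with identical regular 10 Hz trains: per-neuron min ISI is
  # 100 ms, so the rescaled trace must peak at exactly 10 Hz
  sp <- data.frame(population = "MNP_F",
                   neuron_id = rep(1:2, each = 20),
                   time_ms = rep(seq(100, 2000, by = 100), 2))
  tr <- smoothed_rate(sp, "MNP_F", duration_ms = 2000, dt_ms = 1)
  expect_equal(tr$max_inst_rate, 10)
  expect_equal(max(tr$rate), 10, tolerance = 1e-9)

  # worked example: raw peak 50 vs instantaneous 100 -> multiply by 2
  raw_peak <- max(tr$rate) / tr$rescale_factor
  expect_equal(max(tr$rate), raw_peak * tr$rescale_factor)
  fake_factor <- 100 / 50
  expect_equal(fake_factor, 2)
})

test_that("degenerate spike sets are handled: single spike and no spikes", {
  one <- data.frame(population = "MNP_F", neuron_id = 1, time_ms = 500)
  tr <- smoothed_rate(one, "MNP_F", duration_ms = 1000, dt_ms = 1)
  expect_true(is.na(tr$rescale_factor))   # no ISI -> rescaling skipped
  expect_gt(max(tr$rate), 0)
  expect_warning(
    smoothed_rate(one, "MNP_E", duration_ms = 1000, dt_ms = 1),
    "no spikes")
})

test_that("peak detection obeys height, prominence and distance rules", {
  # constant trace: nothing to detect
  expect_length(detect_peaks(make_trace(rep(1, 5000)))$times, 0)

  # two Gaussians, heights 1.0 and 0.3, 2000 ms apart: the 40% height rule
  # keeps only the tall one
  t <- seq(1, 6000)
  x <- exp(-0.5 * ((t - 1500) / 80)^2) + 0.3 * exp(-0.5 * ((t - 3500) / 80)^2)
  pk <- detect_peaks(make_trace(x), min_distance = 1000)
  expect_length(pk$times, 1)
  expect_equal(pk$times, 1500, tolerance = 1)

  # pure sine of period 500 ms under a literal 1000 ms distance floor:
  # every second peak is suppressed; compare against brute-force enumeration
  x <- 1 + sin(2 * pi * t / 500)
  tr <- make_trace(x)
  pk <- detect_peaks(tr, min_distance = 1000)
  oracle <- brute_peaks(x, t, min_distance = 1000)
  expect_equal(pk$times, oracle)
  expect_true(all(diff(pk$times) >= 1000))
  # at the default 100 ms floor every cycle is counted
  pk100 <- detect_peaks(tr, min_distance = 100)
  expect_equal(length(pk100$times), 12)
})

test_that("peak detection equals brute-force enumeration on rough traces", {
  set.seed(5)
  t <- seq(1, 8000)
  for (rep in 1:5) {
    x <- abs(stats::filter(rnorm(8000), rep(1 / 60, 60), sides = 2))
    x[is.na(x)] <- 0
    x <- as.numeric(x)
    pk <- detect_peaks(make_trace(x), min_distance = 300)
    expect_equal(pk$times, brute_peaks(x, t, min_distance = 300))
  }
})

test_that("frequency is the reciprocal mean inter-peak interval", {
  expect_equal(peak_frequency(list(times = c(0, 500, 1000)))$freq_hz, 2)
  f <- peak_frequency(list(times = c(0, 400, 1000)))
  expect_equal(f$period_ms, 500)   # mean of 400 and 600
  expect_equal(f$freq_hz, 2)
  expect_equal(f$n_intervals, 2L)
  miss <- peak_frequency(list(times = 123))
  expect_true(is.na(miss$freq_hz))
  # direct sigma-then-divide recomputation on random peak sets
  set.seed(9)
  for (i in 1:50) {
    tt <- sort(runif(sample(2:12, 1), 0, 10000))
    got <- peak_frequency(list(times = tt))
    expect_equal(got$period_ms, sum(diff(tt)) / (length(tt) - 1))
    expect_equal(got$freq_hz, 1000 / got$period_ms)
  }
})

test_that("burst segmentation recovers symmetric and asymmetric splits", {
  sp <- sine_pair(period = 1000, duration = 10000)
  b <- burst_segments(sp$flexor, sp$extensor)
  expect_equal(unname(b$mean_duration["F"]), 500, tolerance = 1e-2)
  expect_equal(unname(b$mean_duration["E"]), 500, tolerance = 1e-2)

  # 600/400 square-ish alternation
  t <- seq(1, 10000)
  f <- ifelse(t %% 1000 < 600, 2, 0.5)
  b2 <- burst_segments(make_trace(f), make_trace(rep(1, length(t))))
  expect_equal(unname(b2$mean_duration["F"]), 600, tolerance = 2)
  expect_equal(unname(b2$mean_duration["E"]), 400, tolerance = 2)

  # one trace uniformly above the other: no crossings, missing metrics
  b3 <- burst_segments(make_trace(rep(1, 3000)), make_trace(rep(2, 3000)))
  expect_equal(nrow(b3$segments), 0)
  expect_true(all(is.na(b3$mean_duration)))
})

test_that("phase difference follows the midpoint formula with folding", {
  seg <- data.frame(side = c("F", "E", "F"),
                    midpoint = c(0, 500, 1000),
                    start = 0, end = 0, duration = 1)
  expect_equal(phase_difference(seg)$phase_deg, 180)
  seg$midpoint <- c(0, 900, 1000)
  expect_equal(phase_difference(seg)$phase_deg, 36)  # 324 folded

  # random midpoint triples against direct evaluation
  set.seed(31)
  for (i in 1:100) {
    mf1 <- runif(1, 0, 1000); mf2 <- mf1 + runif(1, 200, 1000)
    me <- runif(1, mf1 + 1, mf2 - 1)
    seg <- data.frame(side = c("F", "E", "F"), midpoint = c(mf1, me, mf2),
                      start = 0, end = 0, duration = 1)
    expected <- 360 * (me - mf1) / (mf2 - mf1)
    if (expected > 180) expected <- 360 - expected
    expect_equal(phase_difference(seg)$phase_deg, expected)
    expect_gte(expected, 0); expect_lte(expected, 180)
  }
  # insufficient bursts -> missing
  seg1 <- data.frame(side = c("F", "E"), midpoint = c(0, 500),
                     start = 0, end = 0, duration = 1)
  expect_true(is.na(phase_difference(seg1)$phase_deg))
})

test_that("metrics are invariant to time shifts and common rescaling", {
  sp <- sine_pair(period = 800, duration = 9600)
  base_b <- burst_segments(sp$flexor, sp$extensor)
  base_ph <- phase_difference(base_b)$phase_deg
  base_pk <- detect_peaks(sp$flexor)
  base_fr <- peak_frequency(base_pk)$freq_hz

  # common positive rescaling leaves frequency, bursts and phase unchanged
  f2 <- sp$flexor; f2$rate <- f2$rate * 3.7
  e2 <- sp$extensor; e2$rate <- e2$rate * 3.7
  b2 <- burst_segments(f2, e2)
  expect_equal(b2$mean_duration, base_b$mean_duration)
  expect_equal(phase_difference(b2)$phase_deg, base_ph)
  expect_equal(peak_frequency(detect_peaks(f2))$freq_hz, base_fr)

  # time shift by a whole number of cycles
  shift <- 1600
  idx <- seq_len(length(sp$t) - shift)
  f3 <- make_trace(sp$flexor$rate[idx + shift]); e3 <- make_trace(sp$extensor$rate[idx + shift])
  b3 <- burst_segments(f3, e3)
  expect_equal(b3$mean_duration, base_b$mean_duration, tolerance = 1e-6)
  expect_equal(phase_difference(b3)$phase_deg, base_ph, tolerance = 1e-6)
})

test_that("frequency recovers a known synthetic period within one grid step", {
  for (period in c(333, 400, 500)) {
    t <- seq(1, 10000)
    x <- 1 + sin(2 * pi * t / period)
    fr <- peak_frequency(detect_peaks(make_trace(x), min_distance = 100))
    expect_equal(1000 / fr$freq_hz, period, tolerance = 1)
  }
})
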