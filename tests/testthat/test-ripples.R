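test_that("band-pass filter has the specified design and response", {
  expect_equal(unclass(filter_spec())[c("low", "high", "order")],
               list(low = 200, high = 550, order = 2))
  expect_true(all(bandpass(numeric(1000), 4000) == 0))
  expect_error(bandpass(rnorm(100), 1000, band = c(200, 550)), "Nyquist")

  # single-pass steady-state amplitude at 350 Hz vs the analytic transfer
  # function of the designed digital filter
  fs <- 4000
  bf <- signal::butter(2, c(200, 550) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * 350 / fs)
  H <- abs(sum(bf$b * z^(0:(length(bf$b) - 1))) /
             sum(bf$a * z^(0:(length(bf$a) - 1))))
  t <- (0:(2 * fs)) / fs
  y <- bandpass(sin(2 * pi * 350 * t), fs, zero_phase = FALSE)
  amp <- max(abs(y[(fs):(2 * fs)]))          # past the transient
  expect_equal(amp, H, tolerance = 0.02 * H)
})

test_that("compliant bursts are each detected once", {
  sim <- simulate_eeg(60, 4000, 1, events = burst_events(10), seed = 11)
  f <- bandpass(sim$recording$samples[1, ], 4000)
  ev <- detect_fast_ripples(f, 4000)
  mm <- match_events(ev, sim$truth)
  expect_gte(mm$tp_truth, 9)                  # at worst one miss in ten
  expect_gte(mm$tp_det / max(mm$n_det, 1), 0.8)
  # reported oscillation counts and frequencies are physical
  expect_true(all(ev$n_oscillations >= 4))
  expect_true(all(ev$mean_freq_hz > 180 & ev$mean_freq_hz < 610))
})

test_that("sub-threshold bursts yield no events at the stated margins", {
  ref <- simulate_eeg(60, 4000, 1, seed = 1)
  sd_ref <- sd(bandpass(ref$recording$samples[1, ], 4000))
  spec_fixed <- detector_spec(baseline_sd = sd_ref)
  f4 <- bandpass(pure_burst_trace(4, 6, sd_ref), 4000)
  expect_equal(nrow(detect_fast_ripples(f4, 4000, spec_fixed)), 10)
  f3c <- bandpass(pure_burst_trace(4, 3, sd_ref), 4000)  # too few cycles
  expect_equal(nrow(detect_fast_ripples(f3c, 4000, spec_fixed)), 0)
  f25 <- bandpass(pure_burst_trace(2.5, 6, sd_ref), 4000)  # too weak
  expect_equal(nrow(detect_fast_ripples(f25, 4000, spec_fixed)), 0)
})

test_that("an unreachable threshold detects nothing in noise", {
  sim <- simulate_eeg(30, 4000, 1, seed = 12)
  f <- bandpass(sim$recording$samples[1, ], 4000)
  ev <- detect_fast_ripples(f, 4000,
                            detector_spec(amplitude_ratio = 100))
  expect_equal(nrow(ev), 0)
})

test_that("raising thresholds never increases the event count", {
  for (seed in 13:15) {
    sim <- simulate_eeg(60, 4000, 1, events = burst_events(10), seed = seed)
    f <- bandpass(sim$recording$samples[1, ], 4000)
    n_base <- nrow(detect_fast_ripples(f, 4000))
    for (ratio in c(3.5, 4, 5))
      expect_lte(nrow(detect_fast_ripples(
        f, 4000, detector_spec(amplitude_ratio = ratio))), n_base)
    for (mo in c(5, 6, 8))
      expect_lte(nrow(detect_fast_ripples(
        f, 4000, detector_spec(min_oscillations = mo))), n_base)
  }
})

test_that("detection is invariant under trace rescaling", {
  sim <- simulate_eeg(60, 4000, 1, events = burst_events(10), seed = 16)
  f <- bandpass(sim$recording$samples[1, ], 4000)
  e1 <- detect_fast_ripples(f, 4000)
  for (c in c(1e-3, 17.3, 1e4)) {
    e2 <- detect_fast_ripples(f * c, 4000)
    expect_identical(e1$start_sample, e2$start_sample)
    expect_identical(e1$end_sample, e2$end_sample)
  }
})

test_that("multi-channel wrapper attributes events to their channels", {
  ev <- rbind(burst_events(3, dur = 20),
              transform(burst_events(2, dur = 20), channel = 2,
                        time_s = time_s + 1))
  sim <- simulate_eeg(20, 4000, 2, events = ev, seed = 17)
  out <- detect_ripples(sim$recording)
  expect_true(all(c("E01", "E02") %in% out$channel))
})

test_that("rate summaries follow the stated percentile convention", {
  rs <- summarize_rates(6, 30)
  expect_equal(rs$rates$rate_per_min, 0.2)           # 6 events in 30 min

  rs3 <- summarize_rates(c(3, 6, 9), 30, groups = rep("ctrl", 3))
  gs <- rs3$group_summary
  expect_equal(gs$median, 0.2)
  expect_equal(gs$q25, 0.15)                          # linear interpolation
  expect_equal(gs$q75, 0.25)

  rs0 <- summarize_rates(c(0, 0), 30)
  expect_true(all(rs0$rates$rate_per_min == 0))
  expect_equal(rs0$group_summary$median, 0)
  expect_error(summarize_rates(3, 0), "positive")
})

test_that("traces shorter than the baseline window are rejected", {
  expect_error(detect_fast_ripples(rnorm(100), 4000), "baseline window")
})
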