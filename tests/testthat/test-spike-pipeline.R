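test_that("band-pass filter passes in-band and rejects out-of-band tones", {
  sr <- fixture_sr
  t <- (0:(sr - 1)) / sr
  rms <- function(x) sqrt(mean(x^2))
  tone <- function(f) grn_trace(sin(2 * pi * f * t), sr)
  out50 <- bandpass_filter(tone(50))
  expect_lt(rms(out50$samples) / rms(tone(50)$samples), 0.05)
  out500 <- bandpass_filter(tone(500))
  expect_gt(rms(out500$samples) / rms(tone(500)$samples), 0.80)
  zero <- bandpass_filter(grn_trace(numeric(sr), sr))
  expect_true(all(zero$samples == 0))
  expect_error(bandpass_filter(tone(50), low = 0), "band")
  expect_error(bandpass_filter(tone(50), low = 2000, high = 1000), "band")
  expect_error(bandpass_filter(tone(50), high = sr), "band")
})

test_that("baseline normalization is offset-invariant and kills drift", {
  tr <- make_spike_trace(c(0.5, 1.2, 2.0), seed = 8)
  shifted <- tr
  shifted$samples <- tr$samples + 7.5
  expect_equal(normalize_baseline(tr)$samples,
               normalize_baseline(shifted)$samples, tolerance = 1e-8)
  # pure linear drift, no spikes: the running median tracks it exactly in
  # the interior, so the normalized trace collapses to zero
  n <- 3 * fixture_sr
  drift <- grn_trace(10 * (0:(n - 1)) / fixture_sr, fixture_sr)
  expect_true(all(normalize_baseline(drift)$samples == 0))
  # zero-variance trace: zero out, no division blow-up
  flat <- grn_trace(rep(3.3, n), fixture_sr)
  expect_true(all(normalize_baseline(flat)$samples == 0))
})

test_that("threshold detection recovers injected spikes at 3x noise SD", {
  times <- seq(0.3, 2.55, by = 0.25)  # 10 spikes
  tr <- make_spike_trace(times, amplitude = 0.6, noise_sd = 0.2, seed = 21)
  ev <- detect_spikes(normalize_baseline(bandpass_filter(tr)))
  expect_equal(nrow(ev$events), 10)
  expect_true(all(vapply(times, function(t) {
    any(abs(ev$events$time - t) <= 2e-4)
  }, logical(1))))
  # waveform window: +/- 2 ms at 30 kHz
  expect_equal(ncol(ev$waveforms), 2 * round(0.002 * fixture_sr) + 1)
})

test_that("a threshold above the global maximum finds nothing", {
  tr <- make_spike_trace(c(0.5, 1.0), seed = 3)
  norm <- normalize_baseline(bandpass_filter(tr))
  ev <- detect_spikes(norm, threshold = max(norm$samples) + 1)
  expect_equal(nrow(ev$events), 0)
  expect_error(detect_spikes(norm, threshold = 0), "threshold")
  expect_error(detect_spikes(norm, threshold = -2), "threshold")
})

test_that("peaks closer than the refractory spacing merge to the larger", {
  sr <- fixture_sr
  x <- numeric(sr)
  x[round(0.5 * sr)] <- 5
  x[round(0.5 * sr) + round(0.0005 * sr)] <- 8  # 0.5 ms later, larger
  ev <- detect_spikes(grn_trace(x, sr), threshold = 3)
  expect_equal(nrow(ev$events), 1)
  expect_equal(ev$events$amplitude, 8)
})

test_that("the retention window is half-open [start, end)", {
  ev <- make_events(c(0.05, 0.10, 2.09, 2.10))
  kept <- window_spikes(ev)
  expect_equal(kept$events$time, c(0.10, 2.09))
  expect_equal(nrow(window_spikes(make_events(numeric(0)))$events), 0)
  inside <- make_events(c(0.5, 1.0, 1.5))
  expect_equal(window_spikes(inside)$events, inside$events)
  expect_error(window_spikes(ev, start = 2, end = 1), "start")
})

test_that("amplitude outliers are rejected at mean + 3 SD", {
  # hand oracle on 99 x 1.0 plus one 10.0: mean = 1.09, sd = 0.9 exactly
  # (sum of squared deviations 80.19 over 99), cutoff = 3.79, so exactly
  # the amplitude-10 event goes
  amps <- c(rep(1, 99), 10)
  expect_equal(mean(amps) + 3 * sd(amps), 3.79, tolerance = 1e-12)
  ev <- make_events(seq(0.2, 2.0, length.out = 100), amplitude = amps)
  res <- remove_artifacts(ev)
  expect_equal(res$n_rejected_amplitude, 1)
  expect_equal(res$n_rejected_width, 0)
  expect_false(any(res$events$events$amplitude == 10))
})

test_that("identical amplitudes produce no rejections (zero-SD edge case)", {
  ev <- make_events(seq(0.2, 2.0, length.out = 100), amplitude = 1)
  res <- remove_artifacts(ev)
  expect_equal(res$n_rejected_amplitude, 0)
  expect_equal(res$n_rejected_width, 0)
  expect_equal(nrow(res$events$events), 100)
})

test_that("waveforms wider than 1.5 ms are rejected in step 2", {
  widths <- c(rep(0.8, 50), 2.0, 2.4)
  ev <- make_events(seq(0.2, 2.0, length.out = 52), width_ms = widths)
  res <- remove_artifacts(ev)
  expect_equal(res$n_rejected_width, 2)
  expect_true(all(res$events$events$width_ms <= 1.5))
})

test_that("the 1 s rate counts events in [0.1, 1.1) only", {
  expect_equal(firing_rate(make_events(seq(0.1, 1.0999, length.out = 80))),
               80)
  expect_equal(firing_rate(make_events(numeric(0))), 0)
  expect_equal(firing_rate(make_events(seq(1.1, 2.09, length.out = 30))), 0)
  expect_equal(firing_rate(make_events(c(0.0999, 0.1, 1.0999, 1.1))), 2)
})

test_that("binning yields exactly 20 bins that conserve event counts", {
  b <- bin_rates(make_events(0.15))
  expect_length(b, 20)
  expect_equal(b[1], 1L)
  expect_equal(sum(b), 1L)
  set.seed(5)
  times <- runif(200, 0.1, 2.0999)
  expect_equal(sum(bin_rates(make_events(times))), 200L)
  expect_length(bin_rates(make_events(numeric(0))), 20)
})

test_that("full pipeline conserves counts and the rate equals bins 1-10", {
  cfg <- ephys_sim_config(seed = 7, n_large_artifacts = 2,
                          n_wide_artifacts = 2)
  fr <- firing_record(generate_grn_trace(cfg))
  expect_equal(fr$n_detected,
               fr$n_retained + fr$n_rejected_amplitude +
                 fr$n_rejected_width)
  expect_equal(fr$rate_1s, sum(fr$binned[1:10]))
  expect_equal(sum(fr$binned), fr$n_retained)
})

test_that("pipeline recovers generator ground truth at high SNR", {
  # 10-seed recovery spot check; the full 50-seed sweep runs with the
  # acceptance suite
  for (s in 1:10) {
    tr <- generate_grn_trace(ephys_sim_config(seed = 100 + s))
    fr <- firing_record(tr)
    truth <- tr$truth$spike_times
    truth <- truth[truth >= 0.1 & truth < 2.1]
    m <- match_counts(fr$events$events$time, truth)
    expect_gte(m / length(truth), 0.95)
    expect_gte(m / nrow(fr$events$events), 0.95)
  }
})

test_that("non-responding sensilla are filtered out of rate tables", {
  tab <- expand.grid(sensillum_id = c("s1", "s2"),
                     stimulus = c("water", "sucrose", "NaCl", "quinine",
                                  "caffeine"), stringsAsFactors = FALSE)
  tab$rate_1s <- 10
  tab$rate_1s[tab$sensillum_id == "s2" & tab$stimulus == "quinine"] <- 0
  out <- filter_responsive(tab)
  expect_setequal(unique(out$sensillum_id), "s1")
  expect_equal(attr(out, "dropped"), "s2")
})
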