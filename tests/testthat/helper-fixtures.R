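# Fixtures built in code. The injected-spike builder is deliberately
# independent of the package's own waveform machinery: spikes are simple
# Gaussian lobes so detection tests are checked against an external shape.

fixture_sr <- 30000

# trace with Gaussian-lobe spikes at known times over Gaussian noise
make_spike_trace <- function(times, amplitude = 0.6, noise_sd = 0.2,
                             duration = 3, width_ms = 0.8, sr = fixture_sr,
                             seed = 1) {
  set.seed(seed)
  n <- round(duration * sr)
  x <- rnorm(n, 0, noise_sd)
  sigma <- (width_ms / 1000) / (2 * sqrt(2 * log(2)))
  half <- ceiling(4 * sigma * sr)
  tpl <- amplitude * exp(-((-half:half) / sr)^2 / (2 * sigma^2))
  for (t in times) {
    c0 <- round(t * sr) + 1
    idx <- (c0 - half):(c0 + half)
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + tpl[ok]
  }
  grn_trace(x, sr, bee_id = "fix", sensillum_id = "fix", stimulus = "sucrose")
}

# spike_events from bare times (unit amplitude / width unless given)
make_events <- function(times, amplitude = 1, width_ms = 0.8,
                        sr = fixture_sr) {
  spike_events(data.frame(time = times,
                          amplitude = rep_len(amplitude, length(times)),
                          width_ms = rep_len(width_ms, length(times))),
               sample_rate = sr)
}

# one bee's conditioning log built from explicit correctness flags:
# correct visits are realised as (rewarding, probed); incorrect as
# (rewarding, not probed)
make_conditioning_log <- function(correct_training, correct_test,
                                  bee_id = "beeX", group = "control") {
  mk <- function(correct, phase) {
    data.frame(bee_id = bee_id, group = group, phase = phase,
               bout = (seq_along(correct) - 1) %/% 20 + 1,
               visit_index = seq_along(correct),
               flower_class = "rewarding",
               probed = as.integer(correct), mouthpart_contact = 0L,
               stringsAsFactors = FALSE)
  }
  rbind(mk(correct_training, "training"), mk(correct_test, "test"))
}

match_counts <- function(detected, truth, tol = 3e-4) {
  sum(vapply(truth, function(t) any(abs(detected - t) <= tol), logical(1)))
}
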