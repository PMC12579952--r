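# Spike detection and rate extraction for tip-recording traces:
# band-pass filter -> baseline normalization -> threshold peak detection ->
# retention window -> two-step artifact rejection -> 1 s rate and 100 ms bins.

#' Construct a single-sensillum voltage trace
#'
#' @param samples Numeric vector of voltages (mV for raw traces; normalized
#'   units after [normalize_baseline()]).
#' @param sample_rate Sampling rate in Hz.
#' @param bee_id,sensillum_id Identifiers.
#' @param location `"mid"` or `"tip"`.
#' @param stimulus Stimulus label.
#' @param truth Optional ground-truth list (synthetic traces only).
#' @return An object of class `grn_trace`.
#' @export
grn_trace <- function(samples, sample_rate, bee_id = NA_character_,
                      sensillum_id = NA_character_, location = "mid",
                      stimulus = NA_character_, truth = NULL) {
  if (!is.numeric(samples)) stop("'samples' must be numeric", call. = FALSE)
  check_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 bee_id = bee_id, sensillum_id = sensillum_id,
                 location = location, stimulus = stimulus, truth = truth),
            class = "grn_trace")
}

#' @export
print.grn_trace <- function(x, ...) {
  cat(sprintf("<grn_trace> %.3f s @ %g Hz | bee %s sensillum %s (%s) | stimulus %s\n",
              length(x$samples) / x$sample_rate, x$sample_rate,
              x$bee_id, x$sensillum_id, x$location, x$stimulus))
  invisible(x)
}

with_samples <- function(trace, samples) {
  trace$samples <- samples
  trace
}

#' Zero-phase band-pass filter a trace
#'
#' 4th-order Butterworth band-pass applied forward and backward (zero phase),
#' isolating the 100-1000 Hz band where GRN spike energy lies.
#'
#' @param trace A [grn_trace()].
#' @param low,high Band edges in Hz; requires `0 < low < high < sample_rate/2`.
#' @return The filtered trace (same length and metadata).
#' @export
bandpass_filter <- function(trace, low = 100, high = 1000) {
  stopifnot(inherits(trace, "grn_trace"))
  nyq <- trace$sample_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop(sprintf("invalid band [%g, %g] Hz for Nyquist %g Hz", low, high, nyq),
         call. = FALSE)
  }
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  with_samples(trace, as.numeric(signal::filtfilt(bf, trace$samples)))
}

#' Remove baseline fluctuations and scale to robust noise units
#'
#' Subtracts a running median (51 ms window) to remove slowly varying
#' baseline, then divides by the median absolute deviation of the residual so
#' detection thresholds are comparable across traces. A zero-variance trace
#' maps to all zeros (no division blow-up).
#'
#' @param trace A [grn_trace()].
#' @param window_s Running-median window in seconds (default 0.051).
#' @return The normalized trace.
#' @export
normalize_baseline <- function(trace, window_s = 0.051) {
  stopifnot(inherits(trace, "grn_trace"))
  x <- trace$samples
  if (length(x) == 0) stop("empty trace", call. = FALSE)
  k <- round(window_s * trace$sample_rate)
  if (k %% 2 == 0) k <- k + 1
  k <- max(3L, min(k, if (length(x) %% 2 == 1) length(x) else length(x) - 1L))
  base <- stats::runmed(x, k, endrule = "median")
  resid <- x - base
  s <- stats::mad(resid)
  if (s == 0) return(with_samples(trace, rep(0, length(x))))
  with_samples(trace, resid / s)
}

# Full width at half maximum of the absolute waveform, in ms: the contiguous
# span around the central peak over which |w| stays >= half the peak value
# (so neighbouring spikes inside the +/-2 ms window do not inflate the
# width). |w| is smoothed with a short moving average (~0.23 ms) first so a
# single noise sample near the half-max crossing cannot truncate the span.
waveform_width_ms <- function(waveform, sample_rate, centre = NULL,
                              smooth = 7L) {
  a <- abs(waveform)
  if (length(a) > smooth && smooth > 1) {
    sm <- as.numeric(stats::filter(a, rep(1 / smooth, smooth), sides = 2))
    a <- ifelse(is.na(sm), a, sm)
  }
  if (is.null(centre)) centre <- (length(a) + 1L) %/% 2L
  half <- a[centre] / 2
  if (half <= 0) return(0)
  lo <- centre
  while (lo > 1 && a[lo - 1] >= half) lo <- lo - 1
  hi <- centre
  while (hi < length(a) && a[hi + 1] >= half) hi <- hi + 1
  (hi - lo) / sample_rate * 1000
}

#' Detect spikes as threshold-crossing local maxima
#'
#' Finds local maxima exceeding the threshold, merges peaks closer than the
#' refractory spacing (larger peak wins, ties broken by earlier time) and
#' extracts +/-2 ms waveforms around each peak (edge-padded with the edge
#' value). The automatic threshold is 5x the MAD-based noise estimate of the
#' (normalized) trace, a documented stand-in for the manually set thresholds
#' used at the rig.
#'
#' @param trace A filtered, normalized [grn_trace()].
#' @param threshold Positive detection threshold in normalized units, or
#'   `"auto"`.
#' @param refractory_ms Minimum peak spacing in ms (default 1).
#' @param waveform_ms Half-width of the extracted waveform in ms (default 2).
#' @return A `spike_events` object: list with `events` (data frame of `time`
#'   in seconds, `amplitude`, `width_ms`), a `waveforms` matrix (one row per
#'   event, `2*round(waveform_ms/1000*sample_rate)+1` columns) and
#'   `sample_rate`.
#' @export
detect_spikes <- function(trace, threshold = "auto", refractory_ms = 1,
                          waveform_ms = 2) {
  stopifnot(inherits(trace, "grn_trace"))
  x <- trace$samples
  sr <- trace$sample_rate
  if (identical(threshold, "auto")) threshold <- 5 * stats::mad(x)
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("'threshold' must be positive (or \"auto\")", call. = FALSE)
  }
  n <- length(x)
  peaks <- integer(0)
  if (n >= 3) {
    i <- 2:(n - 1)
    peaks <- i[x[i] > threshold & x[i] > x[i - 1] & x[i] >= x[i + 1]]
  }
  # refractory merge: accept in decreasing amplitude (ties: earlier first)
  if (length(peaks) > 1) {
    gap <- round(refractory_ms / 1000 * sr)
    ord <- order(-x[peaks], peaks)
    accepted <- integer(0)
    for (p in peaks[ord]) {
      if (!length(accepted) || all(abs(accepted - p) >= gap)) {
        accepted <- c(accepted, p)
      }
    }
    peaks <- sort(accepted)
  }
  half <- round(waveform_ms / 1000 * sr)
  wf <- matrix(numeric(0), nrow = 0, ncol = 2 * half + 1)
  width <- numeric(length(peaks))
  if (length(peaks)) {
    padded <- c(rep(x[1], half), x, rep(x[n], half))
    wf <- t(vapply(peaks, function(p) padded[p:(p + 2 * half)],
                   numeric(2 * half + 1)))
    width <- apply(wf, 1, waveform_width_ms, sample_rate = sr)
  }
  spike_events(data.frame(time = (peaks - 1) / sr, amplitude = x[peaks],
                          width_ms = width),
               waveforms = wf, sample_rate = sr)
}

#' Construct a spike-event set
#'
#' @param events Data frame with columns `time` (s), `amplitude`, `width_ms`.
#' @param waveforms Matrix of extracted waveforms, one row per event.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `spike_events`.
#' @export
spike_events <- function(events, waveforms = NULL, sample_rate = 30000) {
  stopifnot(is.data.frame(events),
            all(c("time", "amplitude", "width_ms") %in% names(events)))
  if (is.null(waveforms)) {
    waveforms <- matrix(numeric(0), nrow = nrow(events), ncol = 0)
  }
  structure(list(events = events, waveforms = waveforms,
                 sample_rate = sample_rate),
            class = "spike_events")
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("<spike_events> %d events @ %g Hz\n", nrow(x$events),
              x$sample_rate))
  invisible(x)
}

subset_events <- function(ev, keep) {
  ev$events <- ev$events[keep, , drop = FALSE]
  rownames(ev$events) <- NULL
  if (ncol(ev$waveforms)) ev$waveforms <- ev$waveforms[keep, , drop = FALSE]
  ev
}

#' Retain spikes inside the analysis window
#'
#' Keeps events with `start <= time < end` (half-open). The default window is
#' 0.1 to 2.1 s after recording onset.
#'
#' @param ev A `spike_events` object.
#' @param start,end Window bounds in seconds.
#' @return The windowed `spike_events`.
#' @export
window_spikes <- function(ev, start = 0.1, end = 2.1) {
  stopifnot(inherits(ev, "spike_events"))
  if (!(start < end)) stop("'start' must be < 'end'", call. = FALSE)
  subset_events(ev, ev$events$time >= start & ev$events$time < end)
}

#' Two-step artifact rejection
#'
#' Step 1 removes events whose peak amplitude exceeds the per-trace mean plus
#' `k_sd` standard deviations of peak amplitudes (large-amplitude artifacts).
#' Step 2 removes events whose waveform width (full width at half maximum of
#' the absolute waveform) exceeds `max_width_ms` — 1.5 ms, i.e. 45 samples at
#' 30 kHz (non-spike artifacts).
#'
#' @param ev A `spike_events` object.
#' @param k_sd Amplitude-outlier multiplier (default 3).
#' @param max_width_ms Width bound in ms (default 1.5).
#' @return A list with `events` (retained `spike_events`),
#'   `n_rejected_amplitude` and `n_rejected_width`.
#' @export
remove_artifacts <- function(ev, k_sd = 3, max_width_ms = 1.5) {
  stopifnot(inherits(ev, "spike_events"))
  amp <- ev$events$amplitude
  n <- length(amp)
  if (n == 0) {
    return(list(events = ev, n_rejected_amplitude = 0L, n_rejected_width = 0L))
  }
  s <- stats::sd(amp)
  big <- if (n > 1 && is.finite(s) && s > 0) amp > mean(amp) + k_sd * s
         else rep(FALSE, n)
  ev1 <- subset_events(ev, !big)
  wide <- ev1$events$width_ms > max_width_ms
  list(events = subset_events(ev1, !wide),
       n_rejected_amplitude = sum(big),
       n_rejected_width = sum(wide))
}

#' Mean firing rate over the first second of the analysis window
#'
#' Counts retained events in `[window_start, window_start + 1)` — with the
#' default window, recording time 0.1 to 1.1 s — expressed as spikes/s.
#'
#' @param ev A windowed `spike_events` object.
#' @param window_start Start of the analysis window in seconds.
#' @return Firing rate in spikes/s.
#' @export
firing_rate <- function(ev, window_start = 0.1) {
  stopifnot(inherits(ev, "spike_events"))
  t <- ev$events$time
  sum(t >= window_start & t < window_start + 1)
}

#' Bin spikes into 20 x 100 ms counts
#'
#' Counts events per consecutive 100 ms bin over the 2 s analysis window
#' starting at `window_start`; always exactly `n_bins` bins, whose sum equals
#' the number of windowed events.
#'
#' @param ev A `spike_events` object windowed to the analysis window.
#' @param window_start Start of the first bin in seconds.
#' @param n_bins Number of bins (default 20).
#' @param bin_width Bin width in seconds (default 0.1).
#' @return Integer vector of `n_bins` counts.
#' @export
bin_rates <- function(ev, window_start = 0.1, n_bins = 20, bin_width = 0.1) {
  stopifnot(inherits(ev, "spike_events"))
  edges <- window_start + bin_width * (0:n_bins)
  t <- ev$events$time
  t <- t[t >= edges[1] & t < edges[n_bins + 1]]
  idx <- pmin(floor((t - window_start) / bin_width) + 1, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  as.integer(counts)
}

#' Run the full spike pipeline on a raw trace
#'
#' Filter, normalize, detect, window, reject artifacts and summarize into a
#' firing record: the 1 s rate, the 20 binned counts and per-step rejection
#' counts.
#'
#' @param trace A raw [grn_trace()].
#' @param threshold Detection threshold (normalized units) or `"auto"`.
#' @param low,high Band-pass edges in Hz.
#' @param window Analysis window `c(start, end)` in seconds.
#' @param k_sd Amplitude-rejection multiplier.
#' @return A `firing_record`: list with trace metadata, `rate_1s`, `binned`
#'   (20 counts), `n_detected` (windowed), `n_retained`,
#'   `n_rejected_amplitude`, `n_rejected_width`, and the retained
#'   `spike_events`.
#' @export
firing_record <- function(trace, threshold = "auto", low = 100, high = 1000,
                          window = c(0.1, 2.1), k_sd = 3) {
  filt <- normalize_baseline(bandpass_filter(trace, low, high))
  ev <- detect_spikes(filt, threshold = threshold)
  evw <- window_spikes(ev, window[1], window[2])
  art <- remove_artifacts(evw, k_sd = k_sd)
  kept <- art$events
  structure(list(bee_id = trace$bee_id, sensillum_id = trace$sensillum_id,
                 location = trace$location, stimulus = trace$stimulus,
                 rate_1s = firing_rate(kept, window[1]),
                 binned = bin_rates(kept, window[1]),
                 n_detected = nrow(evw$events),
                 n_retained = nrow(kept$events),
                 n_rejected_amplitude = art$n_rejected_amplitude,
                 n_rejected_width = art$n_rejected_width,
                 events = kept),
            class = "firing_record")
}

#' Tabulate firing records
#'
#' @param records A list of `firing_record` objects.
#' @return A data frame with one row per sensillum x stimulus: identifiers,
#'   `rate_1s`, `bin_01`..`bin_20` and rejection counts.
#' @export
firing_record_table <- function(records) {
  stopifnot(length(records) > 0)
  rows <- lapply(records, function(r) {
    bins <- as.list(r$binned)
    names(bins) <- sprintf("bin_%02d", 1:20)
    c(list(bee_id = r$bee_id, sensillum_id = r$sensillum_id,
           location = r$location, stimulus = r$stimulus,
           rate_1s = r$rate_1s), bins,
      list(n_detected = r$n_detected, n_retained = r$n_retained,
           n_rejected_amplitude = r$n_rejected_amplitude,
           n_rejected_width = r$n_rejected_width))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Flag sensilla that fail to respond to every tastant
#'
#' Mirrors the exclusion of sensilla that did not respond to all four
#' non-water tastants: a sensillum is kept only if its retained firing rate
#' exceeds `min_rate` for every tastant in `require`.
#'
#' @param rate_table Data frame with columns sensillum_id, stimulus, rate_1s.
#' @param require Stimuli that must all show a response (default the four
#'   tastants, water excluded).
#' @param min_rate Minimum rate (spikes/s) counting as a response.
#' @return The rate table restricted to responsive sensilla, with the dropped
#'   sensillum ids in attribute `"dropped"`.
#' @export
filter_responsive <- function(rate_table,
                              require = c("sucrose", "NaCl", "quinine",
                                          "caffeine"),
                              min_rate = 0) {
  ok <- vapply(split(rate_table, rate_table$sensillum_id), function(d) {
    all(require %in% d$stimulus[d$rate_1s > min_rate])
  }, logical(1))
  keep <- names(ok)[ok]
  out <- rate_table[rate_table$sensillum_id %in% keep, , drop = FALSE]
  attr(out, "dropped") <- setdiff(unique(rate_table$sensillum_id), keep)
  out
}
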