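# Synthetic gustatory-sensillum electrophysiology.
#
# Emulates 3 s tip recordings from single antennal sensilla digitized at
# 30 kHz: phasic-tonic GRN spiking (inhomogeneous Poisson, exponentially
# decaying rate), a biphasic spike waveform, Gaussian noise, and optional
# injected artifacts (large-amplitude and over-wide events) so the artifact
# rejection steps downstream can be exercised against ground truth.

#' Configuration for a synthetic GRN tip-recording trace
#'
#' The instantaneous firing rate follows a phasic-tonic profile
#' \eqn{r(t) = tonic + (peak - tonic) e^{-(t - onset)/\tau}} for
#' \eqn{t \ge onset} (and the tonic rate before onset). The default decay
#' constant of 0.13 s brings the rate within 5\% of the tonic level by 0.4 s
#' after stimulus onset, matching the decline-then-stabilize shape of antennal
#' GRN responses.
#'
#' @param sample_rate Sampling rate in Hz (default 30000).
#' @param duration Trace duration in seconds (default 3).
#' @param stimulus_onset Time of stimulus onset in seconds (default 0).
#' @param peak_rate Initial (phasic) firing rate, spikes/s.
#' @param tonic_rate Sustained firing rate, spikes/s; must not exceed
#'   `peak_rate`.
#' @param decay_tau Phasic decay constant in seconds.
#' @param spike_amplitude Peak amplitude of the injected spike waveform, mV.
#' @param spike_width Spike waveform width parameter in ms; must be < 1.5 ms
#'   (the artifact-rejection bound).
#' @param noise_sd Standard deviation of additive Gaussian noise, mV.
#' @param n_large_artifacts Number of injected large-amplitude artifacts
#'   (3.5x the spike amplitude, spike-like width).
#' @param n_wide_artifacts Number of injected wide artifacts (2 ms full width
#'   at half maximum, i.e. wider than the 1.5 ms rejection bound).
#' @param refractory Absolute refractory period in seconds enforced on
#'   injected spike times by thinning (default 2 ms), so injected spikes stay
#'   resolvable as distinct peaks.
#' @param seed Integer RNG seed; fully determines the generated trace.
#' @return An object of class `ephys_sim_config`.
#' @seealso [generate_grn_trace()]
#' @export
ephys_sim_config <- function(sample_rate = 30000, duration = 3,
                             stimulus_onset = 0, peak_rate = 80,
                             tonic_rate = 20, decay_tau = 0.13,
                             spike_amplitude = 0.8, spike_width = 0.8,
                             noise_sd = 0.2, n_large_artifacts = 0,
                             n_wide_artifacts = 0, refractory = 0.002,
                             seed = 1) {
  check_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(stimulus_onset, "stimulus_onset", lower = 0)
  check_number(peak_rate, "peak_rate", lower = 0)
  check_number(tonic_rate, "tonic_rate", lower = 0, upper = peak_rate)
  check_number(decay_tau, "decay_tau", lower = 0, strict_lower = TRUE)
  check_number(spike_amplitude, "spike_amplitude", lower = 0)
  check_number(spike_width, "spike_width", lower = 0, upper = 1.5,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_count(n_large_artifacts, "n_large_artifacts")
  check_count(n_wide_artifacts, "n_wide_artifacts")
  check_number(refractory, "refractory", lower = 0)
  check_count(seed, "seed")
  structure(list(sample_rate = sample_rate, duration = duration,
                 stimulus_onset = stimulus_onset, peak_rate = peak_rate,
                 tonic_rate = tonic_rate, decay_tau = decay_tau,
                 spike_amplitude = spike_amplitude, spike_width = spike_width,
                 noise_sd = noise_sd, n_large_artifacts = n_large_artifacts,
                 n_wide_artifacts = n_wide_artifacts, refractory = refractory,
                 seed = as.integer(seed)),
            class = "ephys_sim_config")
}

#' Phasic-tonic instantaneous firing rate
#'
#' @param t Time in seconds (vectorized).
#' @param cfg An [ephys_sim_config()].
#' @return Instantaneous rate r(t) in spikes/s.
#' @export
grn_rate <- function(t, cfg) {
  r <- rep(cfg$tonic_rate, length(t))
  post <- t >= cfg$stimulus_onset
  r[post] <- cfg$tonic_rate + (cfg$peak_rate - cfg$tonic_rate) *
    exp(-(t[post] - cfg$stimulus_onset) / cfg$decay_tau)
  r
}

# Biphasic difference-of-Gaussians spike template. `width_ms` sets the FWHM of
# the dominant positive lobe; the undershoot lobe peaks at 0.45x so the
# measured full width at half maximum of |w| stays close to width_ms.
spike_template <- function(width_ms, sample_rate, amplitude = 1,
                           biphasic = TRUE) {
  sigma <- (width_ms / 1000) / (2 * sqrt(2 * log(2)))
  half <- max(3L, ceiling(6 * sigma * sample_rate))
  t <- (-half:half) / sample_rate
  w <- exp(-t^2 / (2 * sigma^2))
  if (biphasic) w <- w - 0.45 * exp(-(t - 2 * sigma)^2 / (2 * sigma^2))
  amplitude * w / max(abs(w))
}

# Wide artifact: a half-cycle pulse (default 5 ms, a 100 Hz lobe). Enough of
# its energy sits inside the 100-1000 Hz analysis band that the band-pass
# filter leaves a broad central lobe whose full width at half maximum is
# over 2 ms, well beyond the 1.5 ms spike bound.
wide_artifact_template <- function(sample_rate, amplitude = 1,
                                   duration_ms = 5) {
  n <- round(duration_ms / 1000 * sample_rate)
  if (n %% 2 == 0) n <- n + 1
  t <- seq(0, 1, length.out = n)
  amplitude * sin(pi * t)
}

add_waveform_at <- function(samples, time_s, template, sample_rate) {
  centre <- round(time_s * sample_rate) + 1L
  half <- (length(template) - 1L) %/% 2L
  idx <- (centre - half):(centre + half)
  ok <- idx >= 1L & idx <= length(samples)
  samples[idx[ok]] <- samples[idx[ok]] + template[ok]
  samples
}

#' Generate a synthetic GRN tip-recording trace with ground truth
#'
#' Draws spike times from an inhomogeneous Poisson process with the config's
#' phasic-tonic rate profile (by thinning a homogeneous process at the peak
#' rate), removes events violating the refractory period, injects a biphasic
#' spike waveform at each time on top of Gaussian noise, and optionally adds
#' large-amplitude and wide artifact events. Artifacts are placed inside the
#' downstream analysis window so rejection steps can be validated.
#'
#' @param cfg An [ephys_sim_config()].
#' @param bee_id,sensillum_id Identifiers carried in the trace metadata.
#' @param location Sensillum location, `"mid"` or `"tip"`.
#' @param stimulus Stimulus label (one of water, sucrose, NaCl, quinine,
#'   caffeine by convention; any string is accepted).
#' @return A [grn_trace()] whose `truth` element holds the injected spike
#'   times (`spike_times`, seconds) and an artifact table (`artifacts`, with
#'   columns `time` and `type`).
#' @examples
#' tr <- generate_grn_trace(ephys_sim_config(duration = 1, seed = 7))
#' length(tr$truth$spike_times)
#' @export
generate_grn_trace <- function(cfg, bee_id = "bee01", sensillum_id = "s01",
                               location = c("mid", "tip"),
                               stimulus = "sucrose") {
  if (!inherits(cfg, "ephys_sim_config")) {
    stop("'cfg' must be an ephys_sim_config object", call. = FALSE)
  }
  location <- match.arg(location)
  set.seed(cfg$seed)
  n <- round(cfg$duration * cfg$sample_rate)
  times <- numeric(0)
  if (cfg$peak_rate > 0) {
    n_cand <- stats::rpois(1, cfg$peak_rate * cfg$duration)
    cand <- sort(stats::runif(n_cand, 0, cfg$duration))
    keep <- stats::runif(n_cand) < grn_rate(cand, cfg) / cfg$peak_rate
    cand <- cand[keep]
    # refractory thinning: keep a spike only if >= refractory after the last
    if (length(cand) > 1 && cfg$refractory > 0) {
      kept <- logical(length(cand))
      last <- -Inf
      for (i in seq_along(cand)) {
        if (cand[i] - last >= cfg$refractory) {
          kept[i] <- TRUE
          last <- cand[i]
        }
      }
      cand <- cand[kept]
    }
    times <- cand
  }

  samples <- if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else numeric(n)
  if (cfg$spike_amplitude > 0 && length(times) > 0) {
    tmpl <- spike_template(cfg$spike_width, cfg$sample_rate,
                           amplitude = cfg$spike_amplitude)
    for (tt in times) samples <- add_waveform_at(samples, tt, tmpl, cfg$sample_rate)
  }

  n_art <- cfg$n_large_artifacts + cfg$n_wide_artifacts
  artifacts <- data.frame(time = numeric(0), type = character(0))
  if (n_art > 0) {
    lo <- 0.2
    hi <- max(lo + 0.05, min(cfg$duration - 0.05, 2.0))
    # artifacts >= 10 ms apart and >= 5 ms from any injected spike, so the
    # ground-truth labels stay unambiguous
    at <- numeric(0)
    tries <- 0
    while (length(at) < n_art && tries < 10000) {
      tries <- tries + 1
      cand_t <- stats::runif(1, lo, hi)
      if ((!length(times) || min(abs(times - cand_t)) >= 0.005) &&
          (!length(at) || min(abs(at - cand_t)) >= 0.01)) {
        at <- c(at, cand_t)
      }
    }
    at <- sort(at)
    type <- c(rep("large_amplitude", cfg$n_large_artifacts),
              rep("wide", cfg$n_wide_artifacts))
    artifacts <- data.frame(time = at, type = sample(type))
    big <- spike_template(cfg$spike_width, cfg$sample_rate,
                          amplitude = 3.5 * cfg$spike_amplitude)
    wide <- wide_artifact_template(cfg$sample_rate,
                                   amplitude = 1.4 * cfg$spike_amplitude)
    for (i in seq_len(nrow(artifacts))) {
      tmpl <- if (artifacts$type[i] == "large_amplitude") big else wide
      samples <- add_waveform_at(samples, artifacts$time[i], tmpl,
                                 cfg$sample_rate)
    }
  }

  grn_trace(samples, cfg$sample_rate, bee_id = bee_id,
            sensillum_id = sensillum_id, location = location,
            stimulus = stimulus,
            truth = list(spike_times = times, artifacts = artifacts))
}

#' Default phasic-tonic rate profile for a stimulus and location
#'
#' Qualitative study conditions used by the simulation drivers: DI water
#' elicits the lowest rates everywhere; sucrose and NaCl elicit intermediate
#' responses; the bitter compounds quinine and caffeine elicit the strongest
#' sustained responses at tip sensilla.
#'
#' @param stimulus One of `"water"`, `"sucrose"`, `"NaCl"`, `"quinine"`,
#'   `"caffeine"`.
#' @param location `"mid"` or `"tip"`.
#' @return A list with `peak_rate` and `tonic_rate` (spikes/s).
#' @export
grn_rate_profile <- function(stimulus, location = c("mid", "tip")) {
  location <- match.arg(location)
  base <- switch(stimulus,
    water    = c(peak = 30, tonic = 8),
    sucrose  = c(peak = 80, tonic = 22),
    NaCl     = c(peak = 75, tonic = 20),
    quinine  = c(peak = 85, tonic = 24),
    caffeine = c(peak = 85, tonic = 24),
    stop(sprintf("unknown stimulus '%s'", stimulus), call. = FALSE))
  if (location == "tip" && stimulus %in% c("quinine", "caffeine")) {
    base <- c(peak = 110, tonic = 40)
  }
  list(peak_rate = unname(base["peak"]), tonic_rate = unname(base["tonic"]))
}

#' Simulate a Gamma-distributed firing-rate table
#'
#' Draws per-(sensillum, stimulus) 1 s firing rates from a Gamma generalized
#' linear model with log-linear stimulus, location and interaction effects:
#' rate ~ Gamma(shape, mean = exp(b0 + stimulus + location + interaction)).
#' Used to study family selection and Wald-test calibration.
#'
#' @param n_sensilla Total sensilla, split evenly between mid and tip.
#' @param stimuli Character vector of stimulus labels.
#' @param shape Gamma shape parameter.
#' @param intercept Log mean rate of the first stimulus at mid location.
#' @param stim_effects Named or unnamed numeric vector of log-mean shifts per
#'   stimulus beyond the first (recycled/truncated to length
#'   `length(stimuli) - 1`).
#' @param loc_effect Log-mean shift for tip vs mid.
#' @param interaction Numeric vector of stimulus x tip interaction shifts
#'   (length `length(stimuli) - 1`), default all zero.
#' @param n_bees Number of bees the sensilla are spread over (metadata only).
#' @param seed Integer RNG seed.
#' @return A data frame with columns bee_id, sensillum_id, location, stimulus,
#'   rate_1s (a RateTable).
#' @export
simulate_rate_table <- function(n_sensilla = 26, stimuli = c("water",
                                "sucrose", "NaCl", "quinine", "caffeine"),
                                shape = 5, intercept = log(20),
                                stim_effects = rep(0, length(stimuli) - 1),
                                loc_effect = 0,
                                interaction = rep(0, length(stimuli) - 1),
                                n_bees = 10, seed = 1) {
  check_count(n_sensilla, "n_sensilla", lower = 2)
  set.seed(seed)
  stim_effects <- rep_len(stim_effects, length(stimuli) - 1)
  interaction <- rep_len(interaction, length(stimuli) - 1)
  loc <- rep(c("mid", "tip"), length.out = n_sensilla)
  bee <- sprintf("bee%02d", rep_len(seq_len(n_bees), n_sensilla))
  out <- expand.grid(sensillum = seq_len(n_sensilla),
                     stimulus = stimuli, stringsAsFactors = FALSE)
  out$bee_id <- bee[out$sensillum]
  out$location <- loc[out$sensillum]
  out$sensillum_id <- sprintf("s%02d", out$sensillum)
  si <- match(out$stimulus, stimuli) - 1L    # 0 for reference stimulus
  eff <- ifelse(si == 0, 0, stim_effects[pmax(si, 1)])
  int <- ifelse(si == 0 | out$location == "mid", 0, interaction[pmax(si, 1)])
  mu <- exp(intercept + eff + loc_effect * (out$location == "tip") + int)
  out$rate_1s <- stats::rgamma(nrow(out), shape = shape, rate = shape / mu)
  out[, c("bee_id", "sensillum_id", "location", "stimulus", "rate_1s")]
}

#' Simulate a binned spike-count table with a bee random effect
#'
#' Generates 20 x 100 ms Poisson bin counts per (bee, sensillum, stimulus)
#' from phasic-tonic rate profiles, with a log-normal bee-level random effect,
#' for exercising the temporal Gamma mixed model.
#'
#' @param n_bees Number of bees (one sensillum each by default).
#' @param profiles Named list mapping stimulus label to a list with
#'   `peak_rate`, `tonic_rate` and optionally `decay_tau` (default 0.13 s).
#' @param bee_sd SD of the bee-level log-normal multiplier.
#' @param window_start Start of the analysis window in seconds (bins cover
#'   `window_start` to `window_start + 2`).
#' @param seed Integer RNG seed.
#' @return A data frame with columns bee_id, sensillum_id, stimulus, time_bin
#'   (1..20), count.
#' @export
simulate_bin_table <- function(n_bees = 10,
                               profiles = list(
                                 sucrose = list(peak_rate = 80, tonic_rate = 22),
                                 water = list(peak_rate = 30, tonic_rate = 8)),
                               bee_sd = 0.2, window_start = 0.1, seed = 1) {
  set.seed(seed)
  edges <- window_start + seq(0, 2, by = 0.1)
  rows <- list()
  for (b in seq_len(n_bees)) {
    bee_mult <- exp(stats::rnorm(1, 0, bee_sd))
    for (stim in names(profiles)) {
      pr <- profiles[[stim]]
      tau <- if (is.null(pr$decay_tau)) 0.13 else pr$decay_tau
      # expected count per bin: integral of the phasic-tonic rate
      lam <- vapply(seq_len(20), function(k) {
        a <- edges[k]; b2 <- edges[k + 1]
        pr$tonic_rate * (b2 - a) + (pr$peak_rate - pr$tonic_rate) * tau *
          (exp(-a / tau) - exp(-b2 / tau))
      }, numeric(1))
      counts <- stats::rpois(20, bee_mult * lam)
      rows[[length(rows) + 1L]] <- data.frame(
        bee_id = sprintf("bee%02d", b),
        sensillum_id = sprintf("bee%02d_s1", b),
        stimulus = stim, time_bin = 1:20, count = counts,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
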