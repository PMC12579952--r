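#!/usr/bin/env Rscript
# Simulate the antennal tip-recording cohort: 26 trichodea C/D sensilla
# (13 mid, 13 tip) across 10 bees, each stimulated for 3 s with DI water,
# 100 mM sucrose, 100 mM NaCl, 1 mM quinine and 1 mM caffeine. Stimulus- and
# location-dependent phasic-tonic rates follow grn_rate_profile(); a few
# traces carry injected artifacts so the rejection steps have work to do.
# Traces go to scratch/traces/ as CSV + YAML ground truth with a manifest.

suppressPackageStartupMessages(library(beetaste))

out_dir <- "scratch/traces"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
master_seed <- 20260927L

stimuli <- c("water", "sucrose", "NaCl", "quinine", "caffeine")
# per-bee sensillum layout: 3 bees with 2 mid + 1 tip, 3 with 1 mid + 2 tip,
# 4 with 1 mid + 1 tip -> 13 mid, 13 tip
layout <- c(rep(list(c("mid", "mid", "tip")), 3),
            rep(list(c("mid", "tip", "tip")), 3),
            rep(list(c("mid", "tip")), 4))

manifest <- list()
k <- 0
sens_idx <- 0
for (b in seq_along(layout)) {
  for (si in seq_along(layout[[b]])) {
    loc <- layout[[b]][si]
    sens_idx <- sens_idx + 1
    # sensilla differ in overall responsiveness: log-normal gain (sd 0.3)
    # shared by all five stimuli of one sensillum
    set.seed(derive_seed(master_seed, 9000L + sens_idx))
    gain <- exp(rnorm(1, 0, 0.3))
    for (stim in stimuli) {
      k <- k + 1
      prof <- grn_rate_profile(stim, loc)
      prof$peak_rate <- prof$peak_rate * gain
      prof$tonic_rate <- prof$tonic_rate * gain
      seed <- derive_seed(master_seed, k)
      # roughly one trace in five carries artifacts, as at a real rig
      has_art <- (k %% 5) == 0
      cfg <- ephys_sim_config(peak_rate = prof$peak_rate,
                              tonic_rate = prof$tonic_rate,
                              n_large_artifacts = if (has_art) 1 else 0,
                              n_wide_artifacts = if (has_art) 1 else 0,
                              seed = seed)
      bee_id <- sprintf("bee%02d", b)
      sens_id <- sprintf("bee%02d_s%d", b, si)
      tr <- generate_grn_trace(cfg, bee_id = bee_id, sensillum_id = sens_id,
                               location = loc, stimulus = stim)
      path <- file.path(out_dir, sprintf("%s_%s.csv", sens_id, stim))
      write_trace_csv(tr, path)
      manifest[[k]] <- data.frame(bee_id = bee_id, sensillum_id = sens_id,
                                  location = loc, stimulus = stim,
                                  path = path, n_truth_spikes =
                                    length(tr$truth$spike_times))
    }
  }
}
manifest <- do.call(rbind, manifest)
dir.create("results", showWarnings = FALSE)
write.csv(manifest, "results/trace_manifest.csv", row.names = FALSE)

cat(sprintf("Simulated %d traces (%d sensilla x %d stimuli) to %s\n",
            nrow(manifest), nrow(manifest) / length(stimuli),
            length(stimuli), out_dir))
cat(sprintf("Ground-truth spikes per trace: median %d (range %d-%d)\n",
            median(manifest$n_truth_spikes), min(manifest$n_truth_spikes),
            max(manifest$n_truth_spikes)))
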