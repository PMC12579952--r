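#!/usr/bin/env Rscript
# Simulate the two free-flight experiments.
#
# Preference: 12 naive bees per tastant (sucrose, NaCl, quinine, caffeine)
# forage to 20 landings on six treated + six untreated flowers. Naive bees
# carry no learned values, so their probing is cue-blind (chance level 0.5).
#
# Conditioning: the nine groups of Table-1 structure (control plus
# tastant-positive and tastant-negative per tastant), 10 bees each,
# 70 training visits on six rewarding + six non-rewarding flowers and 20
# unrewarded test visits. Conditioned bees learn by the delta rule
# (learn_rate 0.2, cue salience 1); control bees have no usable surface cue.

suppressPackageStartupMessages(library(beetaste))

dir.create("results", showWarnings = FALSE)
master_seed <- 20260927L
tastants <- c("sucrose", "nacl", "quinine", "caffeine")

pref_logs <- lapply(seq_along(tastants), function(i) {
  p <- forager_params(seed = derive_seed(master_seed, 100L + i))
  log <- generate_visit_log(p, design_spec("preference",
                                           group = tastants[i]),
                            n_bees = 12,
                            bee_prefix = paste0(tastants[i], "_bee"))
  log
})
pref <- do.call(rbind, pref_logs)
write_visit_log(pref, "results/visits_preference.csv")
cat(sprintf("Preference: %d visits from %d bees (%d tastants x 12)\n",
            nrow(pref), length(unique(pref$bee_id)), length(tastants)))

# each tastant panel carries its own simulated control bees (bee ids are
# prefixed by panel so the combined table stays per-bee unique)
cond_logs <- lapply(seq_along(tastants), function(i) {
  simulate_conditioning_cohort(tastants[i], n_bees = 10,
                               seed = derive_seed(master_seed, 200L + i),
                               bee_prefix = paste0(tastants[i], "."))
})
cond <- do.call(rbind, cond_logs)
write_visit_log(cond, "results/visits_conditioning.csv")
cat(sprintf("Conditioning: %d visits from %d bees (4 panels x 3 groups x 10)\n",
            nrow(cond), length(unique(cond$bee_id))))
cat(sprintf("Mouthpart contacts logged: %d of %d visits\n",
            sum(cond$mouthpart_contact), nrow(cond)))
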