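---
title: "Methods: antennal GRN spike analysis and floral surface-chemistry learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antennal GRN spike analysis and floral surface-chemistry learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

beetaste implements two analysis chains used in studies of bumblebee
antennal gustation and free-flight foraging on artificial flowers, together
with seeded synthetic-data generators that stand in for raw recordings and
visit logs. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic data can and cannot tell you about
real recordings.

## 1. The electrophysiology chain

### Signal model

A tip recording from a single antennal taste sensillum is modelled as

    v(t) = sum_i w(t - t_i) + noise(t) [+ artifacts]

where the spike times `t_i` follow an inhomogeneous Poisson process with a
phasic–tonic rate

    r(t) = tonic + (peak - tonic) * exp(-t / tau),

thinned to enforce a 2 ms absolute refractory period. The default decay
constant `tau = 0.13 s` makes the rate fall within 5% of the tonic level by
0.4 s after stimulus onset, the decline-then-stabilize shape typical of
antennal gustatory receptor neuron (GRN) responses. The spike waveform
`w` is a biphasic difference of Gaussians whose positive-lobe full width at
half maximum is the `spike_width` parameter (default 0.8 ms; anything at or
beyond 1.5 ms is by definition an artifact, so the config rejects such
values). Traces default to 3 s at 30 kHz.

Two artifact types can be injected for validating the rejection steps:

* *large-amplitude* artifacts — spike-shaped events at 3.5x the spike
  amplitude;
* *wide* artifacts — a 5 ms half-cycle (100 Hz) pulse at 1.4x the spike
  amplitude. Its energy is concentrated inside the analysis band, so after
  band-pass filtering it survives as a broad lobe whose measured width
  (about 2 ms) exceeds the 1.5 ms spike bound, which is exactly the failure
  mode the width-rejection step exists for.

Artifacts are placed at least 5 ms from injected spikes and 10 ms from each
other so the ground-truth labels stay unambiguous.

### Detection pipeline

`firing_record()` chains the steps; each is exported separately.

1. **Band-pass filter** (`bandpass_filter`): 4th-order Butterworth,
   100–1000 Hz, applied forward–backward (`signal::filtfilt`) for zero
   phase. Only the band is prescribed by the recording protocol; the order
   and zero-phase realization are implementation choices that keep spike
   peaks unshifted.
2. **Baseline normalization** (`normalize_baseline`): subtract a running
   median (51 ms window, `stats::runmed`) and divide by the median absolute
   deviation of the residual. Thresholds are thereafter expressed in robust
   noise units comparable across traces. A zero-variance trace maps to all
   zeros rather than dividing by zero.
3. **Peak detection** (`detect_spikes`): local maxima above threshold.
   The `"auto"` threshold is 5x the MAD-based noise estimate; at the rig
   thresholds were set manually per trace, so the automatic value is a
   documented stand-in and an explicit threshold can be passed instead.
   Peaks closer than 1 ms merge to the larger (ties to the earlier).
   Waveforms of ±2 ms around each peak are extracted with edge padding.
4. **Retention window** (`window_spikes`): half-open `[0.1, 2.1)` s. The
   half-open convention makes the seven 100 ms bins and the 1 s rate nest
   exactly with no double counting at bin edges.
5. **Artifact rejection** (`remove_artifacts`): step 1 removes events with
   peak amplitude above the per-trace mean + 3 SD ("significantly higher
   than the mean" operationalized; `k` configurable); step 2 removes events
   whose waveform width exceeds 1.5 ms — 45 samples at 30 kHz. Width is
   measured as the full width at half maximum of the absolute waveform,
   taken as the contiguous span around the central peak (so a neighbouring
   spike inside the ±2 ms window cannot inflate the width) after a ~0.23 ms
   moving-average smoothing of |w| (so a single noise sample near the
   half-max crossing cannot truncate it).
6. **Rates** (`firing_rate`, `bin_rates`): the 1 s rate counts events in
   `[0.1, 1.1)` — the first second of the analysis window, so the rate
   equals the sum of bins 1–10 by construction — and the temporal profile
   is 20 consecutive 100 ms bins.

The manual visual-inspection step of the original workflow has no
algorithmic counterpart; it is replaced here by the invariant suite
(count conservation, ground-truth recovery at SNR ≥ 3, artifact
specificity), which is run by the tests on every build.

Sensilla that fail to respond to any of the four tastants are dropped from
rate tables by `filter_responsive()`, mirroring the cohort inclusion rule.

### Firing-rate inference

`select_rate_family()` fits `rate_1s ~ stimulus * location` under Gamma
(log link), inverse Gaussian (log link) and Gaussian (identity) families
and picks the family with minimum AIC. The protocol names only the
families; log links for the two positive-support families match the log
link of the temporal mixed model and keep effects multiplicative. Zero
rates (possible on silent traces) would break the positive-support
families, so they are replaced by half a spike per second (0.5 spikes/s)
with a warning.

`wald_terms()` reports type-II Wald chi-square tests per term
(`car::Anova`); `pairwise_marginal_means()` computes estimated marginal
means per stimulus within location on the link scale, all pairwise
differences with Tukey family-wise adjustment (the adjustment used for the
letter displays; configurable), and the between-location contrast per
stimulus.

`fit_temporal_glmm()` fits `count + 1 ~ stimulus * time + (1 | bee)` with a
Gamma distribution and log link via glmmTMB (Laplace approximation); the
+1 offset accommodates empty bins. The random structure is a bee-level
intercept only: a sensillum-level effect is deliberately omitted (its
inclusion did not improve fit in the motivating data set). Fixed effects
are assessed by type-II ANOVA and per-time stimulus contrasts by emmeans.
If the mixed model does not converge the function falls back to the
fixed-effects GLM and flags the report; a degenerate all-constant response
short-circuits to a null report (all chi-squares 0, p = 1) rather than an
optimizer failure.

## 2. The behaviour chain

### Scoring rules

Each landing in the spontaneous-preference design is classified as
*favouring* treated flowers iff the bee probed a treated flower or left an
untreated one without probing; the per-bee *tastant surface response rate*
is the favouring proportion of its 20 landings. Each landing in the
differential-conditioning design is *correct* iff the bee probed a
rewarding flower or left a non-rewarding one. The *success rate* is
computed over each consecutive block of ten training visits (visits 1–10,
…, 61–70) and over the 20 test visits. Under random foraging on a balanced
array both scores have expectation 0.5. Visits with mouthpart contact are
scored normally but counted separately — the design treats oral contact as
a monitored rarity, not an exclusion. Incomplete logs fail loudly (bees
that did not finish the experiment were excluded, not pro-rated).

Proportions are arcsine square-root transformed (`asin(sqrt(p))`,
variance-stabilizing) before inference; chance level transforms to
`pi/4 = 0.785`, printed as 0.79.

### The forager agent

`generate_visit_log()` simulates a Rescorla–Wagner learner. At each visit
the bee draws a flower class uniformly from the balanced 12-flower array
(spatial layout is abstracted away: positions are randomized and flowers
relocated after every visit in the assay, so composition is the only
stable signal) and probes with probability

    p = clamp01(p_probe_init + cue_salience * V(class) + scent_salience * S(class)).

During conditioning training, a probed visit delivers its outcome (sucrose
+1, water −1) and updates the visited class's value by
`V <- V + learn_rate * (reward - V)`. Unprobed visits update nothing: in
an operant free-flight assay the bee receives no reward information about
wells it never sampled. Values of unvisited classes decay by
`forget_rate` (default 0).

The scent channel `S` models marks left on probed flowers. It learns by
the same delta rule but is usable even without a surface-chemistry cue —
it is the mechanism by which control-group bees can climb above chance
during training — and it is reset at the start of the test phase, because
the test presents a fresh, unmarked flower set. This reproduces the
characteristic control-group pattern: above-chance training success that
collapses to chance in the test. `scent_salience` defaults to 0 (off);
cohort simulations can enable it when that confound is wanted.

Test-phase flowers all contain water, trigger no updates and keep their
training-phase class labels, which is how test visits are scored.

Reproducibility: each bee gets its own RNG stream derived from
`(master seed, bee index)` by a linear congruential mix (`derive_seed`),
so cohorts are reproducible independent of generation order, and every
derived seed stays below 2^31.

Default agent settings are the cue-blind baseline (`p_probe_init = 0.5`,
no learning), the chance condition against which both scoring rules are
calibrated. Conditioned cohorts use `learn_rate = 0.2`,
`cue_salience = 1`, the configuration under which late training success
reliably exceeds early success and the downstream model selection
separates conditioned from control groups.

### Behavioural inference

`wilcoxon_vs_random()` tests the transformed response rates two-tailed
against `pi/4`, dropping zero differences. The null distribution is:

* the standard exact signed-rank distribution when the differences are
  untied and n ≤ 25 (`stats::wilcox.test`);
* with ties (or dropped zeros) and n ≤ 15, full enumeration of all 2^n
  sign assignments using average ranks — the randomization null. Five
  equal rates above baseline give W = 15 and exactly p = 2/32 = 0.0625;
* otherwise the normal approximation with continuity correction.

`fit_learning_models()` fits the candidate family of Gaussian GLMs on the
transformed interval success rates (one row per bee per 10-visit
interval), crossing three group structures — all groups share one curve;
control vs conditioned; all three distinct — with three experience
structures — none; the interval index as an additive covariate (the
"learning parameter"); group × experience interaction. The Gaussian
family on the variance-stabilized scale is the default and configurable.
Selection is by AIC with a parsimony rule: the model with fewest
parameters among those within 2 AIC of the minimum. Repeated measures are
handled by modelling the per-interval observations directly; a bee-level
fixed blocking factor is *not* used because bees are nested in groups, so
bee dummies would absorb every between-group term and make the candidate
group structures indistinguishable — the comparison the candidate family
exists to make. The cost is that within-bee correlation is ignored; for
cue-blind bees the interval successes are in fact independent binomials,
and for learners the group signal dominates, so the AIC ordering is
driven by structure rather than correlation.

`test_phase_anova()` runs the one-way ANOVA on transformed test success
across the three groups of one tastant (df 2 and n − 3; 2 and 27 at ten
bees per group), Tukey HSD pairwise comparisons, and a compact letter
display: groups share a letter iff their Tukey p ≥ α, with letters given
by the maximal cliques of the not-significantly-different graph
(Bron–Kerbosch; exact for the small group counts used here).

## 3. What the generators do and do not emulate

The trace generator reproduces the statistical structure the pipeline
assumes — phasic–tonic Poisson spiking, stationary Gaussian noise, a
stereotyped biphasic waveform, isolated artifacts — and provides exact
ground truth. Real tip recordings differ in ways the generator does not
model: inter-spike-interval statistics beyond Poisson-with-refractoriness,
coloured noise and mains interference, waveform drift within a recording,
multiple simultaneously active GRNs per sensillum (the pipeline pools all
threshold crossings into one response, as the protocol did), and
contact/stimulus-onset transients. Passing the recovery suite therefore
shows the pipeline is correct under its own assumptions, not that those
assumptions hold for any particular rig.

The forager agent reproduces chance-level calibration, acquisition curves
and the control-group train/test dissociation, but has no spatial flight
model, no satiation or bout-length variability (bout boundaries fall every
20 visits exactly), and no UV/texture confounds. Mouthpart contacts are
logged as rare independent events (default rate 0.002/visit) without any
behavioural consequence.

Stimulus–location rate profiles used by the cohort driver
(`grn_rate_profile`) encode the qualitative response pattern — water
lowest everywhere, bitter compounds strongest at tip sensilla — and a
log-normal sensillum-level gain (SD 0.3) supplies the between-sensillum
heterogeneity that makes cohort rate tables right-skewed, the regime in
which the Gamma family wins the AIC comparison. None of these values are
fitted to real recordings; they are plausible study conditions, fixed once.

## 4. Numerical choices and problem sizes

* Tolerances: ground-truth spike matching uses 0.3 ms; filter design is
  delegated to `signal::butter`; GLMM estimation is glmmTMB's Laplace
  approximation with its default convergence controls, and convergence is
  verified via the optimizer flag and Hessian positive-definiteness.
* Ties: peak merging keeps the earlier of two equal peaks; parsimony
  selection breaks AIC ties toward fewer parameters, then lower AIC.
* Degenerate inputs: zero-variance traces normalize to zero; empty event
  sets bin to twenty zeros; all-zero bin tables yield a null temporal
  report; an all-at-chance Wilcoxon sample is flagged degenerate with
  p = 1.
* Test problem sizes (chosen to exercise every property in a few minutes):
  chance calibrations pool ≥ 10,000 simulated visits; spike recovery runs
  50 seeded traces of 3 s; type-I error checks use 1000 simulated nulls
  for the Wilcoxon and ANOVA and 10,000 for the Wald test, whose true size
  (≈ 0.058 with estimated dispersion and a chi-square reference at 130
  observations) sits close enough to the band edge that the extra
  replicates are needed to measure it stably; selection sweeps use 100
  replicates. The analysis drivers simulate the full study layout: 26
  sensilla × 5 stimuli, 48 preference bees, and 4 × 30 conditioning bees.

## 5. Known limitations

* The automatic detection threshold replaces per-trace manual thresholds;
  on low-SNR traces a manual value may be needed, and the package makes no
  attempt to flag marginal SNR beyond the responsiveness filter.
* The learning-model family treats per-interval observations as
  exchangeable within bee; a random-effects formulation would be the next
  refinement if within-bee correlation mattered for a given data set.
* The Wald chi-square tests are mildly anticonservative at the cohort's
  sample size (size ≈ 0.058 at nominal 0.05); an F reference would be
  better calibrated but is not what the motivating analysis used.
* Scoring assumes complete logs with strictly increasing visit indices;
  irregular field data must be cleaned upstream of `read_visit_log()`.

## 6. Running the full analysis

The `analysis/` scripts chain the pieces end to end and write their tables
under `results/`:

```{r}
# from the repository root
# Rscript analysis/01_simulate_ephys.R     # traces + ground truth
# Rscript analysis/02_spike_pipeline.R     # rates.csv, bins.csv, spike_qc.csv
# Rscript analysis/03_firing_stats.R       # family AIC, Wald, contrasts, GLMM
# Rscript analysis/04_simulate_foragers.R  # visit logs for both designs
# Rscript analysis/05_behaviour_stats.R    # Wilcoxon, learning models, ANOVA
# Rscript analysis/06_figures.R            # temporal and learning-curve figures
```
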