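Package: beetaste
Title: Antennal Taste Electrophysiology and Floral Surface-Chemistry Learning Analyses for Bumblebees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for two analysis chains used in studies of bumblebee
    (Bombus terrestris) antennal gustation and free-flight foraging. The first
    chain detects gustatory receptor neuron spikes in tip-recording voltage
    traces (band-pass filtering, baseline normalization, threshold peak
    detection, two-step artifact rejection, windowed firing rates and 100 ms
    binning) and models firing rates with AIC-selected generalized linear
    models, Wald tests, estimated-marginal-mean contrasts and a Gamma mixed
    model for temporal bins. The second chain scores free-flight visit logs
    from spontaneous-preference and differential-conditioning experiments
    (favouring/correct classification, tastant surface response rates,
    success-rate curves at 10-visit intervals), and runs one-sample Wilcoxon
    tests on arcsine square-root transformed proportions, AIC-selected
    learning-curve models and test-phase ANOVA with Tukey post hoc letter
    groupings. Seeded synthetic-data generators (an inhomogeneous-Poisson
    phasic-tonic spiking model and a Rescorla-Wagner foraging agent) provide
    ground-truthed inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    car,
    emmeans,
    glmmTMB,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
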