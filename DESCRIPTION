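Package: oddballAEP
Title: Auditory Oddball Evoked-Potential Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for passive auditory oddball event-related
    potential (ERP) studies. Builds the oddball stimulus sequence (frequent
    1000 Hz standards, rare 2000 Hz deviants), simulates multi-channel EEG
    for two-group cohorts with parametric P1/N1/P2/N2/P3a components,
    habituation and change-detection structure, and clinical scores with
    configurable correlations to latent ERP parameters; preprocesses
    continuous recordings (band-pass and notch filtering, bad-channel
    rules, average re-reference, spatial artifact-component removal,
    epoching, amplitude-based rejection, baseline correction); extracts
    per-subject condition averages, z-normalized peak amplitudes and
    latencies, and the mismatch-negativity difference wave at Cz and FCz;
    and runs the inference layer (mixed-design ANOVAs with an age
    covariate, one-way ANCOVA, covariate-adjusted Pearson correlations
    with Benjamini-Hochberg false-discovery-rate control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
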