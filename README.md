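# oddballAEP

Auditory oddball evoked-potential simulation and analysis in R.

## The problem

In passive auditory oddball studies, a train of frequent "standard"
tones (1000 Hz) is interrupted by rare "deviant" tones (2000 Hz). The
EEG response time-locked to each tone — the auditory evoked potential
(AEP) — carries stereotyped components (P1, N1, P2, N2, P3a), and two
derived phenomena index sensory learning: **habituation** (attenuation
of the response from the first standard of a trial, S1, to the standard
immediately preceding the deviant, SPrecDev) and **change detection**
(enhancement from SPrecDev to the deviant, Dev), including the
**mismatch negativity** (MMN), the most negative deflection of the
Dev − SPrecDev difference wave between 100 and 350 ms. These markers
are studied in neurodevelopmental conditions such as Fragile X
syndrome, where exaggerated N1/P2 amplitudes, prolonged latencies and
absent habituation have been reported and related to clinical severity.

`oddballAEP` implements the complete analysis chain for such studies —
paradigm construction, preprocessing, peak extraction, and the
inference layer — together with a synthetic-data generator that
produces cohorts and EEG with known ground truth, so every stage is
testable without any data download.

## What the package computes

- **Paradigm** (`generate_session`): trials of 4–9 standards followed by
  one deviant at position 5–10; with 10 repetitions per position the
  session has 450 tones, 390 standards (86.67%) and 60 deviants
  (13.33%), at a 1070 ms onset asynchrony (70 ms tone + 1000 ms
  interval).
- **Synthetic EEG** (`simulate_cohort`, `simulate_recording`,
  `simulate_evoked`): each component is a signed Gaussian deflection
  `polarity · A · exp(−(t−λ)²/2σ²)`; amplitudes apply group ratios, age
  slopes, per-group habituation factors (SPrecDev/S1) and deviance
  boosts (Dev/SPrecDev), plus an extra deviant negativity generating
  the MMN. Continuous recordings add 1/f noise, 60 Hz line noise,
  frontal blink transients, and optional flat/noisy channels. Clinical
  scores are generated with calibrated partial correlations to latent
  ERP parameters.
- **Preprocessing** (`preprocess_recording`): zero-phase 0.5–150 Hz
  band-pass + 60 Hz notch, bad channels at SD < 2 or > 120 µV, average
  re-reference, spatial artifact-component removal, −1000..1000 ms
  epochs, ±200 µV rejection, −200..600 ms AEP window with −200..0 ms
  baseline.
- **Features** (`average_by_class`, `znormalize_subject`,
  `detect_peak`, `compute_mmn`, `extract_features`): per-subject
  z-normalized condition averages; P1 (50–150 ms, +), N1 (80–150, −),
  P2 (150–250, +), N2 (200–400, −), P3a (250–450, +) window extrema at
  Cz and FCz.
- **Inference** (`mixed_anova_covariate`, `ancova_oneway`,
  `partial_pearson`, `fdr_bh`, `correlation_screen`): 2×2 mixed-design
  ANOVAs (condition × group) with a mean-centred age covariate and Type
  III sums of squares, reporting F, df, p and partial eta squared
  (SS_effect/(SS_effect+SS_error)) with Bonferroni pairwise contrasts;
  one-way ANCOVA for the MMN; sex- (and age-) adjusted Pearson
  correlations with Benjamini–Hochberg FDR at 5% within clinical-domain
  families.

## Worked example

```r
library(oddballAEP)

cfg <- run_config(seed = 7, n_clinical = 10, n_control = 10)
run <- run_pipeline(cfg, outdir = "out")
subset(run$anovas, roi == "Cz" & component == "N1" & measure == "amp" &
         analysis == "habituation")
```

```
    analysis roi component measure  n       effect      F df1 df2       p   peta2
 habituation  Cz        N1     amp 20       within 6.9792   1  17 0.01720 0.29075
 habituation  Cz        N1     amp 20 within:group 10.486   1  17 0.00483 0.38155
 habituation  Cz        N1     amp 20   within:age 4.3503   1  17 0.05237 0.20378
 habituation  Cz        N1     amp 20        group 0.2302   1  17 0.63749 0.01336
 habituation  Cz        N1     amp 20          age 0.1166   1  17 0.73695 0.00681
```

With the default generator the control group habituates (SPrecDev =
0.8 × S1) while the clinical group does not, and the run recovers the
habituation × group interaction even at n = 10 per group
(F₍₁,₁₇₎ = 10.5, p = .005, η²ₚ = .38). The group main effect on this
small run is not significant: per-subject z-normalization deliberately
equates overall amplitude scale, so the clinical 1.5× N1 ratio
survives only as a change in relative component structure
(standardized effect ≈ 1.3 SD), reliably detected at the 30-per-group
size the recovery suite uses but not guaranteed at n = 10.
`make_report(run)` renders grand-average plots (S1 vs SPrecDev and
SPrecDev vs Dev per group) and the FDR-flagged correlation table.

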