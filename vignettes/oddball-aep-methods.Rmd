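---
title: "Simulating and analyzing auditory oddball evoked potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing auditory oddball evoked potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oddballAEP)
```

## The design

A passive auditory oddball session consists of trials of repeated
1000 Hz standard tones ending in a single 2000 Hz deviant, the deviant
falling at position 5–10 of its trial. Ten repetitions of each deviant
position give 450 tones per session — 390 standards (86.67%) and 60
deviants (13.33%). Tones last 70 ms (10 ms rise/fall) and are separated
by 1000 ms of silence, so consecutive onsets are 1070 ms apart; the
inter-trial interval equals the interstimulus interval, so the session
is a single uninterrupted tone train. Three stimulus classes enter the
analysis: the first standard of each trial (S1), the standard
immediately preceding the deviant (SPrecDev), and the deviant (Dev).
Habituation is the S1→SPrecDev attenuation; change detection the
SPrecDev→Dev enhancement; the mismatch negativity (MMN) is the most
negative deflection of the Dev − SPrecDev difference wave in
100–350 ms.

One phrasing ambiguity had to be resolved: a description of "ten
different trials ... presented 10 times" is incompatible with the
450/390/60 tone counts unless it means six deviant-position types with
ten repetitions each, which is what `generate_session()` implements
(45 tones per position-type set, times 10). Trial order is a seeded
uniform permutation; no further constraints (such as minimum spacing of
equal positions) are imposed because none are part of the design.

```{r paradigm}
s <- generate_session(seed = 1)
unlist(session_counts(s))
```

## The generator

Each ERP component is a signed Gaussian deflection
$\mathrm{pol}_c \, A_c \exp(-(t-\lambda_c)^2 / 2\sigma_c^2)$. Gaussians
were chosen because the analysis consumes only window extrema:
a smooth unimodal bump makes every downstream quantity (peak value,
peak latency, habituation ratio) analytically predictable, which the
oracle tests exploit. Default parameters (vertex microvolts, S1 of a
control subject at the reference age of 16):

```{r specs}
component_specs()
```

Latency means sit inside the canonical search windows (P1 most
positive 50–150 ms, N1 most negative 80–150 ms, P2 most positive
150–250 ms, N2 most negative 200–400 ms, P3a most positive 250–450 ms);
amplitude means and SDs (~20% of the mean) are in the range typical of
vertex AEPs in school-age and adult cohorts.

The effect structure (`effect_config()`) encodes the clinical
phenotype the cohort emulates, in the direction reported for Fragile X
syndrome: exaggerated N1 (×1.5) and P2 (×1.4) with reduced P1 (×0.8)
in the clinical group, a +5 ms latency shift, habituation
(SPrecDev = 0.8 × S1) in controls but none in the clinical group
(factor 1.0), a deviance boost (×1.2 on N1/P2/N2/P3a) in controls
only, a larger deviant-locked extra negativity in the clinical group
(1.5 vs 1.0 µV, centred at 225 ms so the MMN difference wave peaks
inside 100–350 ms), and component magnitudes declining with age
(e.g. −0.12 µV/year for N1, positive for P3a). Because every component
of a class scales by the same habituation factor, the SPrecDev
template is exactly 0.8 × the S1 template for controls — the factor is
recoverable to machine precision from noise-free features, which the
tests assert.

Spatial structure is a per-channel gain vector, not a head model: Cz
and FCz carry gain 1 and the pattern is zero-mean across the default
20-channel 10–20 montage (polarity inversion at temporal/occipital
sites, as in real average-referenced auditory topographies), so
average re-referencing leaves the vertex ERP unchanged. Blinks use a
separate frontal-weighted pattern whose correlation with the ERP
pattern is low (|r| ≈ 0.18), keeping artifact removal and signal
preservation separable.

Demographics follow the reference cohort shape: 41 clinical subjects
(ages ≈ 17 ± 8, truncated to 7–34, ~76% male) and 46 controls
(≈ 15 ± 10, truncated to 5–30, ~46% male). Clinical scores are linear
functions of a latent component parameter plus Gaussian noise, mixed so
the population partial correlation (controlling sex, and age for
instruments without age-based norms) equals a configured target; the
default score model is the global null (all targets 0), the regime in
which false-discovery control is assessed.

### Noise

Two noise scales are exposed. `pink_noise_sd` (default 20 µV) is the
broadband 1/f background of the raw continuous recording, on top of
which 60 Hz line noise (5 µV), Poisson blink transients (5/min,
150 µV frontal) and optional flat/noisy channels are added.
`trial_noise_sd` (default 5 µV) is the residual evoked-band noise per
single trial after filtering and artifact removal — the quantity that
actually limits evoked averages. Trial-to-trial amplitude variability
of the components themselves is not separately parameterized (the
literature the design draws on does not quantify it); the trial noise
subsumes it.

The default of 5 µV was fixed by design arithmetic before any recovery
suite was run: with 60 trials per class the evoked noise per sample is
$5/\sqrt{60} \approx 0.65$ µV; the habituation contrast
(S1 − SPrecDev difference of group means) is 0.2 × 6 µV = 1.2 µV on N1,
so the per-subject difference score has SD
$\approx \sqrt{2 \times 0.65^2 + (0.2 \times 1.2)^2} \approx 0.95$ µV
and the standardized interaction effect is ≈ 1.25, which at 30
subjects per group gives > 95% power at α = .05 — comfortably above
the 90% the recovery suite requires, without being noiseless.

### The trial-average shortcut

Cohort-level simulations generate per-class evoked waveforms directly
as template + noise scaled by $1/\sqrt{n_\text{trials}}$
(`simulate_evoked()`). For stationary Gaussian noise this is
*distributionally identical* to averaging n independent single-trial
epochs, not an approximation, so power and type-I studies over
hundreds of replicate cohorts stay cheap (a 60-subject replicate takes
well under a second). The single-trial path (`simulate_epochs()`) and
the full continuous-recording path (`simulate_recording()` →
`preprocess_recording()`) are exercised by their own tests, including
an end-to-end check that the noise-free chain returns the generator
template at Cz within 2% RMS (the residual being filter ripple).

## Preprocessing decisions

The stage order is fixed: filter → bad channels → average re-reference
→ artifact removal → epoch → amplitude rejection → crop/baseline.
Choices the source description leaves open were resolved as follows:

- **Zero-phase filtering** (forward–backward Butterworth; 2nd-order
  high-pass, 4th-order low-pass 150 Hz, 2nd-order ±2 Hz notch at
  60 Hz): causal filters displace peak latencies, which are endpoints
  of the analysis. DC is removed explicitly per channel before
  filtering. The 0.5 Hz high-pass is interpreted as the *passband
  edge*, with the half-amplitude (−6 dB) point at 0.25 Hz — the
  convention of the standard EEG filtering tools. This matters for
  oddball trains: the stimulus repetition fundamental sits at
  ≈ 0.93 Hz (1070 ms onset asynchrony), and a filter with −6 dB at
  0.5 Hz itself would attenuate that component of the evoked train to
  ~85% and visibly distort class averages; with the passband-edge
  design the noise-free chain reproduces templates at Cz within 2%
  RMS, which the suite asserts.
- **Fully automatic rules replace manual review** (visual channel and
  epoch inspection, manual component selection): a tested pipeline
  cannot contain manual steps. The automatic thresholds are the stated
  ones (SD < 2 / > 120 µV channels, ±200 µV epochs).
- **Artifact removal is contract-level**: the signal is decomposed
  into spatial principal components; components whose spatial pattern
  correlates |r| ≥ 0.8 with the blink template, or whose time course
  correlates ≥ 0.5 with detected blink activity, are removed. Blink
  detection requires template-weighted transients to exceed a physical
  floor (100 µV) so evoked responses — an order of magnitude smaller —
  never trigger it; components carrying negligible variance are never
  flagged (their rotation vectors are arbitrary). On synthetic data
  with known blinks this removes > 50% of frontal blink-band amplitude
  while distorting the event-locked Cz average by < 1% RMS.
- **Bad channels are dropped, not interpolated**; if an ROI channel is
  dropped the subject's features for that ROI are missing and logged.
- **Epoch rejection precedes baseline correction**, applied on the
  full −1000..1000 ms epochs, matching the stated stage order.
- Sample indexing is 0-based at the recording level; epoch windows are
  half-open `[start, end)` in ms; time 0 is stimulus onset.

## Feature extraction decisions

- **Averaging precedes normalization**: single trials are averaged per
  class, then one mean and SD per subject and channel — pooled over the
  concatenated S1/SPrecDev/Dev averages across the full −200..600 ms
  window — standardize all three conditions. Pooling across conditions
  (rather than normalizing each condition separately) preserves the
  within-subject condition contrasts that habituation and change
  detection quantify; normalizing per condition would erase them.
  The pooled mean/SD are retained so physical units can be recovered.
- **Peak detection is a pure window extremum** with inclusive
  endpoints and earliest-latency tie-breaking; no local-maximum
  (zero-derivative) requirement is imposed. "Semi-automatic" peak
  picking becomes fully deterministic, which is what makes the
  exhaustive-scan oracle test possible.
- **The MMN is computed after normalization** (difference of
  normalized Dev and SPrecDev), matching the stated step order in
  which normalization is the last preprocessing act before component
  definitions; all peak amplitudes, including the MMN, are therefore
  in z units throughout the inference layer.
- Note that z-normalization deliberately removes between-subject
  amplitude scale; associations targeted at *latent* (microvolt-scale)
  parameters are therefore assessed on the latent parameters
  themselves, and the normalized features carry the within-subject
  contrast structure.

## Inference decisions

- The 2×2 mixed-design ANOVA with covariate uses the exact
  general-linear-model split for a two-level within factor: group and
  age effects are tested on subject means `(a+b)/2`, condition effects
  (within, within×group, within×age) on differences `a−b`, with
  sum-coded group contrasts and a mean-centred covariate (Type III sums
  of squares; unbalanced groups weighted equally). With a constant
  covariate the classical mixed ANOVA is recovered exactly, which the
  suite verifies against an explicit sums-of-squares oracle at 1e-10.
  Sphericity corrections are unnecessary for two-level within factors.
- Degenerate designs resolve deterministically: a zero effect sum of
  squares gives F = 0 (even when the error term is also zero), and a
  variable fully explained by covariates has partial r = 0, rather
  than propagating 0/0.
- Bonferroni pairwise contrasts multiply by the size of the stated
  contrast set only (2: group at each condition level, or condition in
  each group).
- Partial Pearson correlations residualize both variables on the
  covariates and use df = n − 2 − k. Sex is always a covariate; age is
  added for score instruments without age-based norms (in the default
  score set: all but the NVIQ-like and adaptive scales).
- The FDR family definition is one Benjamini–Hochberg family per
  clinical domain (cognition, autistic symptoms, adaptive behavior,
  social avoidance, anxiety/depression, ADHD), mirroring how such
  screens are reported per domain; the grouping is configurable.
- Missing features are excluded listwise per analysis, with per-
  analysis n reported (reported degrees of freedom varying across
  components are consistent with per-analysis exclusions, which cannot
  be reconstructed exactly).

## Problem sizes and what the suites show

The recovery suites run at the cohort sizes the design targets:
30 subjects per group and 60 trials per class for the habituation
(control factor 0.8 vs clinical 1.0) and group-amplitude (N1 ×1.5)
analyses — 100 replicates for power, 400 for the null rejection rate —
and 41 clinical subjects for the correlation screen (200 replicates
each for the null and the r = 0.5 pair, 50 cohorts of n = 1000 for
bias). Full-cohort runs in the examples use the default 41/46 split.

Passing suites show that the pipeline recovers the parameters *the
generator realizes*: Gaussian components on stationary Gaussian noise,
linear score models, exact class templates. Real EEG departs from this
in ways the generator does not emulate — non-stationary and
non-Gaussian background activity, latency jitter and amplitude drift
across trials, volume-conducted artifact residuals, imperfect
time-locking — so the suites validate the implementation, not the
field performance of the thresholds.

## The interface

The package is a library, not a shell tool: `run_config()` →
`run_pipeline()` → `make_report()` compose the whole chain, and each
stage is exported for standalone use. Recordings round-trip through a
minimal 16-bit EDF writer/reader (written here because no installed R
package covers EDF), events and cohorts through TSV/CSV, and
configurations through YAML.

```{r pipeline, eval = FALSE}
cfg <- run_config(seed = 7, n_clinical = 10, n_control = 10)
run <- run_pipeline(cfg, outdir = "out")
make_report(run, outdir = "out")
```

## Known limitations

- No biophysical forward model; topography is a gain vector, so
  spatial analyses beyond the two ROIs are out of scope.
- The spatial decomposition for artifact removal is PCA-based; heavily
  correlated artifact/signal topographies would defeat it (the blink
  and ERP patterns used here are nearly orthogonal by design).
- The EDF writer covers the subset of the format the package produces
  (uniform sampling rate, no annotations).
- Latency effects are modelled as a constant group shift; latency
  habituation/change-detection effects are not generated, so latency
  ANOVAs on synthetic data test only the null and group-shift paths.
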