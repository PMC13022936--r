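#' Default ERP component specifications
#'
#' One row per canonical auditory component. Each deflection is generated
#' as a signed Gaussian bump `polarity * A * exp(-(t - lambda)^2 / (2
#' sigma^2))`. Search windows are the analysis windows used for peak
#' extraction: P1 most positive 50--150 ms, N1 most negative 80--150 ms,
#' P2 most positive 150--250 ms, N2 most negative 200--400 ms, P3a most
#' positive 250--450 ms.
#'
#' Amplitude means/SDs are in microvolts at the vertex (Cz gain 1);
#' latencies in ms post-onset. `amplitude_mean` is the magnitude of the
#' deflection for the first standard (S1) of a control subject at the
#' reference age; group ratios, habituation, deviance boosts and age
#' slopes act on it multiplicatively/additively (see [effect_config()]).
#'
#' @return A data.frame with columns `name`, `polarity` (+1/-1),
#'   `latency_mean`, `latency_sd`, `width` (Gaussian sigma, ms),
#'   `amplitude_mean`, `amplitude_sd` (uV), `win_lo`, `win_hi` (ms).
#' @export
component_specs <- function() {
  data.frame(
    name = c("P1", "N1", "P2", "N2", "P3a"),
    polarity = c(1, -1, 1, -1, 1),
    latency_mean = c(100, 115, 200, 290, 330),
    latency_sd = c(8, 8, 10, 12, 12),
    width = c(15, 18, 25, 35, 40),
    amplitude_mean = c(3, 6, 4, 3, 2),
    amplitude_sd = c(0.6, 1.2, 0.8, 0.6, 0.4),
    win_lo = c(50, 80, 150, 200, 250),
    win_hi = c(150, 150, 250, 400, 450),
    stringsAsFactors = FALSE
  )
}

#' Group/condition/age effect structure for the generator
#'
#' Encodes the phenotype contrasts the simulated cohort realizes, in the
#' direction reported for Fragile X syndrome versus neurotypical controls:
#' exaggerated N1/P2 with reduced P1 in the clinical group, habituation
#' (SPrecDev amplitude = `habituation_factor` x S1 amplitude) present in
#' controls but absent in the clinical group, a deviance boost
#' (Dev = `deviance_boost` x SPrecDev, applied to N1/P2/N2/P3a) present in
#' controls, extra deviant-locked negativity (`mmn_extra`, uV) in the
#' 100--350 ms range producing the mismatch negativity, and a linear age
#' slope on component magnitudes (uV/year, centred at `age_ref`).
#'
#' @param group_amp_ratio Named vector, clinical/control amplitude ratio
#'   per component.
#' @param group_latency_shift Clinical latency shift, ms.
#' @param habituation_factor Named vector (`clinical`, `control`),
#'   SPrecDev/S1 amplitude ratio; must lie in (0, 2].
#' @param deviance_boost Named vector (`clinical`, `control`),
#'   Dev/SPrecDev amplitude ratio for N1/P2/N2/P3a.
#' @param age_amp_slope Named vector, uV/year change in component
#'   magnitude.
#' @param mmn_extra Named vector (`clinical`, `control`), uV of added
#'   negativity on deviants.
#' @param age_ref Reference age (years) at which `amplitude_mean` applies.
#' @return A list of class `effect_config`.
#' @export
effect_config <- function(group_amp_ratio = c(P1 = 0.8, N1 = 1.5, P2 = 1.4,
                                              N2 = 1.0, P3a = 1.0),
                          group_latency_shift = 5,
                          habituation_factor = c(clinical = 1.0, control = 0.8),
                          deviance_boost = c(clinical = 1.0, control = 1.2),
                          age_amp_slope = c(P1 = -0.05, N1 = -0.12, P2 = -0.08,
                                            N2 = -0.05, P3a = 0.03),
                          mmn_extra = c(clinical = 1.5, control = 1.0),
                          age_ref = 16) {
  stopifnot(
    all(habituation_factor > 0), all(habituation_factor <= 2),
    all(group_amp_ratio > 0), all(deviance_boost > 0)
  )
  structure(
    list(
      group_amp_ratio = group_amp_ratio,
      group_latency_shift = group_latency_shift,
      habituation_factor = habituation_factor,
      deviance_boost = deviance_boost,
      age_amp_slope = age_amp_slope,
      mmn_extra = mmn_extra,
      age_ref = age_ref
    ),
    class = "effect_config"
  )
}

#' Noise and artifact specification for the EEG generator
#'
#' `pink_noise_sd` is the broadband 1/f background of the continuous
#' recording; `trial_noise_sd` is the residual evoked-band noise per
#' single trial used by the trial/evoked-level generators (the background
#' that survives filtering and artifact removal). `blink_rate` is
#' events/minute of stereotyped frontal-weighted blink transients.
#' `n_flat_channels`/`n_noisy_channels` designate channels rendered flat
#' (SD well below 2 uV) or pathologically noisy (SD well above 120 uV) so
#' the bad-channel rules have something to catch.
#'
#' @param pink_noise_sd,trial_noise_sd,line_noise_amp,blink_amp Amplitudes
#'   in uV.
#' @param blink_rate Blinks per minute.
#' @param n_flat_channels,n_noisy_channels Channel counts.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(pink_noise_sd = 20, trial_noise_sd = 5,
                       line_noise_amp = 5, blink_rate = 5, blink_amp = 150,
                       n_flat_channels = 0, n_noisy_channels = 0) {
  vals <- c(pink_noise_sd, trial_noise_sd, line_noise_amp, blink_rate,
            blink_amp, n_flat_channels, n_noisy_channels)
  stopifnot(all(vals >= 0))
  structure(
    list(
      pink_noise_sd = pink_noise_sd, trial_noise_sd = trial_noise_sd,
      line_noise_amp = line_noise_amp, blink_rate = blink_rate,
      blink_amp = blink_amp, n_flat_channels = n_flat_channels,
      n_noisy_channels = n_noisy_channels
    ),
    class = "noise_spec"
  )
}

#' Default 10-20 montage and spatial gain patterns
#'
#' Nineteen standard 10-20 sites plus FCz (both regions of interest, Cz
#' and FCz, carry gain 1). `erp_gain` is the vertex-weighted, zero-mean
#' (dipolar) spatial pattern of the evoked response -- zero-mean across
#' the montage so that average re-referencing leaves the vertex ERP
#' unchanged, with polarity inversion at temporal/occipital sites as in
#' auditory ERP topographies; `blink_gain` is the frontal-weighted
#' pattern of ocular artifacts.
#'
#' @return `default_montage()`: character vector of channel names.
#'   `erp_gain()`/`blink_gain()`: named numeric vectors over a montage.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FCz",
    "T7", "C3", "Cz", "C4", "T8",
    "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
}

#' @rdname default_montage
#' @param montage Channel names.
#' @export
erp_gain <- function(montage = default_montage()) {
  base <- c(Fp1 = -0.4629, Fp2 = -0.4629, F7 = -0.3660, F3 = 0.1220,
            Fz = 0.5120, F4 = 0.1220, F8 = -0.3660, FCz = 1,
            T7 = -0.2680, C3 = 0.4150, Cz = 1, C4 = 0.4150,
            T8 = -0.2680, P7 = -0.3660, P3 = 0.0240, Pz = 0.2200,
            P4 = 0.0240, P8 = -0.3660, O1 = -0.4629, O2 = -0.4629)
  g <- base[montage]
  g[is.na(g)] <- 0
  names(g) <- montage
  g
}

#' @rdname default_montage
#' @export
blink_gain <- function(montage = default_montage()) {
  base <- c(Fp1 = 1, Fp2 = 1, F7 = 0.5, F3 = 0.45, Fz = 0.5, F4 = 0.45,
            F8 = 0.5, FCz = 0.3, T7 = 0.1, C3 = 0.12, Cz = 0.1, C4 = 0.12,
            T8 = 0.1, P7 = 0.03, P3 = 0.03, Pz = 0.03, P4 = 0.03,
            P8 = 0.03, O1 = 0, O2 = 0)
  g <- base[montage]
  g[is.na(g)] <- 0
  names(g) <- montage
  g
}
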