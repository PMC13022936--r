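# Parametric ERP waveform and EEG generators.

# Time axis of the AEP analysis window: [-200, 600) ms at 1000 Hz.
aep_time <- function() seq(-200, 599)

# Amplitude scaling of a component for a stimulus class, given the
# group's habituation factor and deviance boost. Steady-state standards
# (other_standard) carry the habituated amplitude, like SPrecDev.
class_scale <- function(comp, stim_class, group, effects) {
  key <- if (group == "clinical") "clinical" else "control"
  h <- effects$habituation_factor[[key]]
  b <- effects$deviance_boost[[key]]
  switch(stim_class,
    S1 = 1,
    SPrecDev = h,
    other_standard = h,
    Dev = h * if (comp %in% c("N1", "P2", "N2", "P3a")) b else 1,
    stop("invalid-label: unknown stim_class ", stim_class)
  )
}

# Resolve a subject's latent component parameters; if the subject row has
# no latent columns, fall back to the deterministic (noise-free)
# population values implied by specs + effects.
subject_latents <- function(subject, specs, effects) {
  amp <- lat <- numeric(nrow(specs))
  names(amp) <- names(lat) <- specs$name
  for (i in seq_len(nrow(specs))) {
    comp <- specs$name[i]
    acol <- paste0("amp_", comp)
    lcol <- paste0("lat_", comp)
    if (acol %in% names(subject) && !is.na(subject[[acol]][1])) {
      amp[comp] <- subject[[acol]][1]
      lat[comp] <- subject[[lcol]][1]
    } else {
      ratio <- if (subject$group[1] == "clinical") {
        effects$group_amp_ratio[[comp]]
      } else 1
      shift <- if (subject$group[1] == "clinical") {
        effects$group_latency_shift
      } else 0
      age <- if ("age" %in% names(subject)) subject$age[1] else effects$age_ref
      amp[comp] <- max(specs$amplitude_mean[i] * ratio +
        effects$age_amp_slope[[comp]] * (age - effects$age_ref), 0.05)
      lat[comp] <- specs$latency_mean[i] + shift
    }
  }
  list(amp = amp, lat = lat)
}

#' Noise-free ERP template for one subject and stimulus class
#'
#' The evoked response is a sum of signed Gaussian deflections, one per
#' component: `polarity * A * exp(-(t - lambda)^2 / (2 sigma^2))`, where
#' the amplitude `A` applies the subject's latent S1 magnitude and the
#' class scaling (habituation factor for SPrecDev/steady-state standards,
#' additionally the deviance boost for N1/P2/N2/P3a on deviants). For
#' deviants an extra negativity of depth `mmn_extra` (Gaussian, centre
#' 225 ms, sigma 50 ms) is added, producing a mismatch-negativity
#' difference wave inside 100--350 ms. The channel dimension is a pure
#' gain vector (Cz and FCz carry gain 1).
#'
#' @param subject One-row data.frame with at least `group` (and
#'   optionally `age` and latent `amp_*`/`lat_*` columns from
#'   [simulate_subjects()]).
#' @param stim_class `"S1"`, `"SPrecDev"`, `"Dev"` or
#'   `"other_standard"`.
#' @param specs Component table ([component_specs()]).
#' @param effects An [effect_config()].
#' @param channel_gain Named per-channel gain vector ([erp_gain()]).
#' @return Matrix channels x 800 (time -200..599 ms at 1000 Hz), in uV,
#'   with attribute `time_ms`.
#' @export
erp_template <- function(subject, stim_class, specs = component_specs(),
                         effects = effect_config(),
                         channel_gain = erp_gain()) {
  if (nrow(specs) == 0L) stop("invalid-config: empty component specs")
  if (!stim_class %in% c("S1", "SPrecDev", "Dev", "other_standard")) {
    stop("invalid-label: unknown stim_class ", stim_class)
  }
  t <- aep_time()
  lt <- subject_latents(subject, specs, effects)
  wave <- numeric(length(t))
  for (i in seq_len(nrow(specs))) {
    comp <- specs$name[i]
    a <- lt$amp[comp] *
      class_scale(comp, stim_class, subject$group[1], effects)
    wave <- wave + specs$polarity[i] * a *
      exp(-(t - lt$lat[comp])^2 / (2 * specs$width[i]^2))
  }
  if (stim_class == "Dev") {
    key <- if (subject$group[1] == "clinical") "clinical" else "control"
    wave <- wave - effects$mmn_extra[[key]] * exp(-(t - 225)^2 / (2 * 50^2))
  }
  out <- outer(unname(channel_gain), wave)
  rownames(out) <- names(channel_gain)
  attr(out, "time_ms") <- t
  out
}

#' Simulate per-condition evoked averages directly
#'
#' Generates the per-class trial average of `n_trials` epochs without
#' materializing single trials: for stationary Gaussian noise, the mean
#' of `n` independent realizations is distributionally identical to one
#' realization scaled by `1/sqrt(n)`, so the evoked equals the noise-free
#' template plus pink noise with per-sample SD
#' `trial_noise_sd / sqrt(n_trials)`. This is the fast path used by
#' cohort-level simulations; the trial-level path is
#' [simulate_epochs()].
#'
#' @inheritParams erp_template
#' @param n_trials Trials averaged per class.
#' @param classes Stimulus classes to produce.
#' @param noise A [noise_spec()] (only `trial_noise_sd` is used here).
#' @param channels Channels to simulate (must be in the gain vector).
#' @param seed Integer seed.
#' @return Named list of [new_evoked()] objects (uV).
#' @export
simulate_evoked <- function(subject, n_trials = 60,
                            classes = c("S1", "SPrecDev", "Dev"),
                            specs = component_specs(),
                            effects = effect_config(),
                            noise = noise_spec(),
                            channels = c("Cz", "FCz"),
                            channel_gain = erp_gain(), seed = 1) {
  gain <- channel_gain[channels]
  if (any(is.na(gain))) stop("invalid-montage: unknown channel")
  with_seed(seed, {
    out <- lapply(classes, function(cl) {
      tpl <- erp_template(subject, cl, specs, effects, gain)
      sdv <- noise$trial_noise_sd / sqrt(n_trials)
      if (sdv > 0) {
        for (ch in seq_len(nrow(tpl))) {
          tpl[ch, ] <- tpl[ch, ] + pink_noise(ncol(tpl), sdv)
        }
      }
      new_evoked(unclass(tpl[, , drop = FALSE]), aep_time(), cl, n_trials,
                 channel_names = channels, normalized = FALSE)
    })
    names(out) <- classes
    out
  })
}

#' Simulate single-trial epochs for one subject
#'
#' Trial-level counterpart of [simulate_evoked()]: each epoch is the
#' class template plus independent pink noise of SD `trial_noise_sd`.
#'
#' @inheritParams simulate_evoked
#' @param n_per_class Epochs per stimulus class.
#' @return An [new_epoch_set()] over -200..599 ms.
#' @export
simulate_epochs <- function(subject, n_per_class = 60,
                            classes = c("S1", "SPrecDev", "Dev"),
                            specs = component_specs(),
                            effects = effect_config(),
                            noise = noise_spec(),
                            channels = c("Cz", "FCz"),
                            channel_gain = erp_gain(), seed = 1) {
  gain <- channel_gain[channels]
  if (any(is.na(gain))) stop("invalid-montage: unknown channel")
  t <- aep_time()
  lab <- rep(classes, each = n_per_class)
  dat <- array(0, c(length(lab), length(channels), length(t)))
  with_seed(seed, {
    tpls <- lapply(classes, function(cl) {
      erp_template(subject, cl, specs, effects, gain)
    })
    names(tpls) <- classes
    for (e in seq_along(lab)) {
      tpl <- tpls[[lab[e]]]
      for (ch in seq_along(channels)) {
        dat[e, ch, ] <- tpl[ch, ] +
          if (noise$trial_noise_sd > 0) {
            pink_noise(length(t), noise$trial_noise_sd)
          } else 0
      }
    }
  })
  new_epoch_set(dat, t, lab, channels, window = c(-200, 600))
}

#' Simulate a continuous multi-channel oddball recording
#'
#' Builds the full-session signal: event-locked ERP templates superposed
#' on 1/f (pink) background noise, a 60 Hz line-noise sinusoid,
#' stereotyped frontal-weighted blink transients (Poisson arrivals), and
#' optionally designated flat and noisy channels. A 1.5 s pre/post roll
#' keeps all epochs inside the recording. Ground truth (blink onset
#' samples and the artifact-free signal) is attached as attributes so
#' cleaning stages can be validated.
#'
#' @inheritParams simulate_evoked
#' @param session An `oddball_session` from [generate_session()].
#' @param montage Channel names; must include Cz and FCz.
#' @param sr Sampling rate (Hz).
#' @param keep_truth Attach `clean` signal and `blink_onsets` attributes.
#' @return An [new_recording()] with the session's events mapped to
#'   samples.
#' @export
simulate_recording <- function(subject, session,
                               specs = component_specs(),
                               effects = effect_config(),
                               noise = noise_spec(),
                               montage = default_montage(),
                               sr = 1000, seed = 1, keep_truth = TRUE) {
  if (!all(c("Cz", "FCz") %in% montage)) {
    stop("invalid-montage: montage must include Cz and FCz")
  }
  gain <- erp_gain(montage)
  bgain <- blink_gain(montage)
  pre <- round(1.5 * sr)
  onset_samp <- pre + round(session$onset * sr / 1000)
  n_samp <- max(onset_samp) + round(0.6 * sr) + round(1.5 * sr)
  nch <- length(montage)

  clean <- matrix(0, nch, n_samp, dimnames = list(montage, NULL))
  tpls <- lapply(c("S1", "SPrecDev", "Dev", "other_standard"), function(cl) {
    erp_template(subject, cl, specs, effects, gain)
  })
  names(tpls) <- c("S1", "SPrecDev", "Dev", "other_standard")
  off <- aep_time() * sr / 1000
  for (e in seq_len(nrow(session))) {
    idx <- onset_samp[e] + off + 1  # 1-based columns
    ok <- idx >= 1 & idx <= n_samp
    cl <- session$stim_class[e]
    clean[, idx[ok]] <- clean[, idx[ok]] + tpls[[cl]][, ok]
  }

  sig <- clean
  blink_onsets <- integer(0)
  with_seed(seed, {
    if (noise$pink_noise_sd > 0) {
      for (ch in seq_len(nch)) {
        sig[ch, ] <- sig[ch, ] + pink_noise(n_samp, noise$pink_noise_sd)
      }
    }
    if (noise$line_noise_amp > 0) {
      tt <- (seq_len(n_samp) - 1) / sr
      phase <- stats::runif(1, 0, 2 * pi)
      line <- noise$line_noise_amp * sin(2 * pi * 60 * tt + phase)
      sig <- sig + matrix(line, nch, n_samp, byrow = TRUE)
    }
    if (noise$blink_rate > 0 && noise$blink_amp > 0) {
      minutes <- n_samp / sr / 60
      nb <- stats::rpois(1, noise$blink_rate * minutes)
      if (nb > 0) {
        blink_onsets <- sort(sample.int(n_samp, nb))
        half <- round(0.3 * sr)
        shape_t <- (-half):half
        shape <- exp(-shape_t^2 / (2 * (0.08 * sr)^2))
        for (b in blink_onsets) {
          idx <- b + shape_t
          ok <- idx >= 1 & idx <= n_samp
          amp <- noise$blink_amp * stats::runif(1, 0.8, 1.2)
          sig[, idx[ok]] <- sig[, idx[ok]] +
            outer(unname(bgain), amp * shape[ok])
        }
      }
    }
    aux <- setdiff(montage, c("Cz", "FCz"))
    if (noise$n_flat_channels > 0) {
      flat <- utils::tail(aux, noise$n_flat_channels)
      for (ch in flat) {
        sig[ch, ] <- stats::rnorm(n_samp, 0, 0.5)
      }
    }
    if (noise$n_noisy_channels > 0) {
      left <- setdiff(aux, utils::tail(aux, noise$n_flat_channels))
      noisy <- utils::head(left, noise$n_noisy_channels)
      for (ch in noisy) {
        sig[ch, ] <- sig[ch, ] + stats::rnorm(n_samp, 0, 200)
      }
    }
  })

  events <- data.frame(
    onset_sample = onset_samp,
    stim_class = session$stim_class,
    role = session$role,
    trial_index = session$trial_index,
    stringsAsFactors = FALSE
  )
  rec <- new_recording(sig, sr, events, reference = "Cz")
  if (keep_truth) {
    attr(rec, "clean") <- clean
    attr(rec, "blink_onsets") <- blink_onsets
  }
  rec
}
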