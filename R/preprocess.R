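# Preprocessing chain for continuous oddball EEG. Stage order is fixed:
# filter -> bad channels -> average re-reference -> artifact-component
# removal -> epoch -> amplitude rejection -> crop + baseline.

#' Band-pass and notch filtering
#'
#' Removes DC per channel, then applies zero-phase (forward-backward)
#' Butterworth filters: a 2nd-order high-pass whose half-amplitude
#' (-6 dB) point sits at `hp/2` -- the passband-edge convention of the
#' standard EEG filter designs, which keeps the stimulus-train
#' fundamental and slow evoked components inside the passband -- a
#' 4th-order low-pass at `lp`, and a 2nd-order band-stop notch of
#' +/- 2 Hz around `notch`. Zero-phase filtering is used so component
#' latencies are not displaced.
#'
#' @param rec An [new_recording()].
#' @param hp High-pass passband edge in Hz (half-amplitude at `hp/2`).
#' @param lp Low-pass cutoff in Hz (must be below Nyquist).
#' @param notch Notch centre frequency in Hz (NULL to skip).
#' @return The filtered recording.
#' @export
bandpass_notch <- function(rec, hp = 0.5, lp = 150, notch = 60) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (lp >= rec$sr / 2) stop("invalid-filter: low-pass cutoff at or above Nyquist")
  ny <- rec$sr / 2
  bf_hp <- signal::butter(2, (hp / 2) / ny, type = "high")
  bf_lp <- signal::butter(4, lp / ny, type = "low")
  bf_no <- if (!is.null(notch)) {
    signal::butter(2, c(notch - 2, notch + 2) / ny, type = "stop")
  } else NULL
  for (ch in seq_len(nrow(rec$signal))) {
    x <- rec$signal[ch, ]
    x <- x - mean(x)
    x <- signal::filtfilt(bf_hp, x)
    x <- signal::filtfilt(bf_lp, x)
    if (!is.null(bf_no)) x <- signal::filtfilt(bf_no, x)
    rec$signal[ch, ] <- x
  }
  rec
}

#' Flag flat or excessively noisy channels
#'
#' Channels whose sample standard deviation is below `sd_lo` (flat
#' signal) or above `sd_hi` are flagged and excluded from all later
#' stages.
#'
#' @param rec An [new_recording()] with at least 2 channels.
#' @param sd_lo,sd_hi Bounds in microvolts.
#' @return Character vector of flagged channel names.
#' @export
detect_bad_channels <- function(rec, sd_lo = 2, sd_hi = 120) {
  stopifnot(inherits(rec, "eeg_recording"), nrow(rec$signal) >= 2)
  sds <- apply(rec$signal, 1, stats::sd)
  bad <- rec$channel_names[sds < sd_lo | sds > sd_hi]
  if (length(bad) == length(rec$channel_names)) {
    stop("data-quality: all channels flagged bad")
  }
  bad
}

#' @rdname detect_bad_channels
#' @details `flag_bad_channels()` runs the detection and returns the
#'   recording with `bad_channels` set.
#' @export
flag_bad_channels <- function(rec, sd_lo = 2, sd_hi = 120) {
  rec$bad_channels <- union(rec$bad_channels,
                            detect_bad_channels(rec, sd_lo, sd_hi))
  rec
}

#' Re-reference retained channels to their average
#'
#' Subtracts, at every sample, the mean across retained (non-bad)
#' channels from each retained channel, so the retained-channel mean is
#' identically zero. Idempotent.
#'
#' @param rec An [new_recording()]; bad channels must already be
#'   flagged.
#' @return The re-referenced recording (`reference = "average"`).
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  keep <- retained_channels(rec)
  if (length(keep) < 2) stop("invalid-input: fewer than 2 retained channels")
  m <- colMeans(rec$signal[keep, , drop = FALSE])
  rec$signal[keep, ] <- sweep(rec$signal[keep, , drop = FALSE], 2, m)
  rec$reference <- "average"
  rec
}

#' Remove ocular artifact components by spatial decomposition
#'
#' Decomposes the retained-channel signal into spatial components
#' (principal components of the channel covariance), flags components
#' whose spatial pattern correlates with the blink template
#' (`|r| >= spatial_thresh`) or whose time course correlates with
#' detected blink activity (`|r| >= temporal_thresh`, evaluated only
#' when the template-weighted frontal signal shows super-threshold
#' transients), and reconstructs the signal without the flagged
#' components. If the decomposition fails the recording is passed
#' through unmodified with attribute `artifact_flagged = TRUE`.
#'
#' @param rec A re-referenced [new_recording()].
#' @param blink_template Named spatial pattern of ocular artifacts over
#'   the montage (defaults to [blink_gain()]).
#' @param spatial_thresh,temporal_thresh Absolute-correlation
#'   thresholds.
#' @param blink_detect_uv Physical floor (uV) a template-weighted
#'   transient must exceed to count as blink activity; keeps the
#'   temporal criterion from firing on evoked responses, which are an
#'   order of magnitude smaller than ocular artifacts.
#' @return The cleaned recording with attribute `n_components_removed`.
#' @export
remove_artifact_components <- function(rec,
                                       blink_template = blink_gain(rec$channel_names),
                                       spatial_thresh = 0.8,
                                       temporal_thresh = 0.5,
                                       blink_detect_uv = 100) {
  stopifnot(inherits(rec, "eeg_recording"))
  keep <- retained_channels(rec)
  tmpl <- blink_template[keep]
  res <- tryCatch({
    X <- rec$signal[keep, , drop = FALSE]
    pc <- stats::prcomp(t(X), center = TRUE, scale. = FALSE)
    rot <- pc$rotation            # channels x comps
    sco <- pc$x                   # samples x comps
    # only components carrying real variance are candidates (rotation
    # vectors of near-zero components are arbitrary)
    cand <- pc$sdev^2 > 1e-6 * sum(pc$sdev^2)
    spat <- abs(apply(rot, 2, function(v) stats::cor(v, tmpl)))
    y <- as.numeric(tmpl %*% X)   # template-weighted frontal signal
    dev <- y - stats::median(y)
    thr <- max(5 * stats::mad(y), blink_detect_uv)
    temp <- rep(FALSE, ncol(rot))
    if (any(dev > thr)) {
      b <- as.numeric(dev > 0.6 * thr)
      temp <- abs(apply(sco, 2, function(s) stats::cor(s, b))) >= temporal_thresh
    }
    flag <- which((spat >= spatial_thresh | temp) & cand)
    if (length(flag)) {
      Xc <- t(t(X) - sco[, flag, drop = FALSE] %*%
                t(rot[, flag, drop = FALSE]))
      rec$signal[keep, ] <- Xc
    }
    attr(rec, "n_components_removed") <- length(flag)
    rec
  }, error = function(e) {
    warning("artifact decomposition failed; recording passed through: ",
            conditionMessage(e))
    attr(rec, "artifact_flagged") <- TRUE
    rec
  })
  res
}

#' Cut stimulus-locked epochs from a continuous recording
#'
#' One epoch per event of a requested class over the half-open window
#' `[window[1], window[2])` ms relative to onset. Events whose window
#' falls outside the recording are skipped and counted in the
#' `n_skipped` attribute. Only retained channels are epoched.
#'
#' @param rec An [new_recording()] with events.
#' @param classes Stimulus classes to epoch.
#' @param window `c(start, end)` in ms relative to stimulus onset.
#' @return An [new_epoch_set()].
#' @export
epoch_recording <- function(rec, classes = c("S1", "SPrecDev", "Dev"),
                            window = c(-1000, 1000)) {
  stopifnot(inherits(rec, "eeg_recording"), !is.null(rec$events))
  ev <- rec$events[rec$events$stim_class %in% classes, , drop = FALSE]
  if (nrow(ev) == 0L) stop("empty-selection: no events of the requested classes")
  keep <- retained_channels(rec)
  step <- 1000 / rec$sr
  time_ms <- seq(window[1], window[2] - step, by = step)
  rel <- round(time_ms * rec$sr / 1000)
  n_samp <- ncol(rec$signal)

  first <- ev$onset_sample + rel[1] + 1
  last <- ev$onset_sample + rel[length(rel)] + 1
  ok <- first >= 1 & last <= n_samp
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    message(n_skipped, " event(s) too close to the recording edge; skipped")
  }
  ev <- ev[ok, , drop = FALSE]
  if (nrow(ev) == 0L) stop("empty-selection: all requested events out of bounds")

  dat <- array(0, c(nrow(ev), length(keep), length(rel)))
  for (e in seq_len(nrow(ev))) {
    idx <- ev$onset_sample[e] + rel + 1
    dat[e, , ] <- rec$signal[keep, idx]
  }
  out <- new_epoch_set(dat, time_ms, ev$stim_class, keep, window = window)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Reject epochs exceeding an absolute amplitude limit
#'
#' Sets `keep_mask` to FALSE for every epoch with any sample outside
#' `[-limit, +limit]` on any retained channel, and records the kept-trial
#' percentage per stimulus class in the `kept_pct` attribute.
#'
#' @param ep An [new_epoch_set()].
#' @param limit Absolute amplitude limit in microvolts.
#' @return The epoch set with an updated `keep_mask`.
#' @export
reject_epochs <- function(ep, limit = 200) {
  stopifnot(inherits(ep, "epoch_set"))
  if (length(ep$stim_class) == 0L) stop("empty-input: no epochs")
  bad <- apply(abs(ep$data) > limit, 1, any)
  ep$keep_mask <- ep$keep_mask & !bad
  kept <- tapply(ep$keep_mask, ep$stim_class, mean) * 100
  attr(ep, "kept_pct") <- kept
  if (any(tapply(ep$keep_mask, ep$stim_class, sum) == 0)) {
    stop("data-quality: a stimulus class lost all epochs to rejection")
  }
  ep
}

#' Crop epochs to the AEP window and apply baseline correction
#'
#' Restricts epochs to `aep_window` (half-open, ms) and subtracts, per
#' epoch and channel, the mean over the half-open `baseline` interval,
#' so the baseline mean of the output is exactly zero.
#'
#' @param ep An [new_epoch_set()].
#' @param aep_window Analysis window `c(start, end)` ms; must lie inside
#'   the epoch window.
#' @param baseline Baseline interval `c(start, end)` ms; must lie inside
#'   `aep_window`.
#' @return The cropped, baseline-corrected epoch set.
#' @export
crop_and_baseline <- function(ep, aep_window = c(-200, 600),
                              baseline = c(-200, 0)) {
  stopifnot(inherits(ep, "epoch_set"))
  if (baseline[1] < aep_window[1] || baseline[2] > aep_window[2]) {
    stop("invalid-config: baseline outside the AEP window")
  }
  if (aep_window[1] < ep$window[1] || aep_window[2] > ep$window[2]) {
    stop("invalid-config: AEP window outside the epoch window")
  }
  sel <- ep$time_ms >= aep_window[1] & ep$time_ms < aep_window[2]
  dat <- ep$data[, , sel, drop = FALSE]
  t_new <- ep$time_ms[sel]
  bsel <- t_new >= baseline[1] & t_new < baseline[2]
  bl <- apply(dat[, , bsel, drop = FALSE], c(1, 2), mean)
  dat <- sweep(dat, c(1, 2), bl)
  out <- new_epoch_set(dat, t_new, ep$stim_class, ep$channel_names,
                       keep_mask = ep$keep_mask, window = aep_window)
  attr(out, "kept_pct") <- attr(ep, "kept_pct")
  out
}

#' Run the full preprocessing chain on one recording
#'
#' Applies, in order: [bandpass_notch()], [flag_bad_channels()],
#' [rereference_average()], [remove_artifact_components()],
#' [epoch_recording()], [reject_epochs()], [crop_and_baseline()].
#'
#' @param rec An [new_recording()].
#' @param hp,lp,notch Filter settings.
#' @param sd_lo,sd_hi Bad-channel bounds (uV).
#' @param reject_limit Epoch rejection limit (uV).
#' @param classes Stimulus classes to keep.
#' @param epoch_window,aep_window,baseline Windows in ms.
#' @return A cleaned, cropped, baseline-corrected [new_epoch_set()].
#' @export
preprocess_recording <- function(rec, hp = 0.5, lp = 150, notch = 60,
                                 sd_lo = 2, sd_hi = 120, reject_limit = 200,
                                 classes = c("S1", "SPrecDev", "Dev"),
                                 epoch_window = c(-1000, 1000),
                                 aep_window = c(-200, 600),
                                 baseline = c(-200, 0)) {
  rec <- bandpass_notch(rec, hp, lp, notch)
  rec <- flag_bad_channels(rec, sd_lo, sd_hi)
  rec <- rereference_average(rec)
  rec <- remove_artifact_components(rec)
  ep <- epoch_recording(rec, classes, epoch_window)
  ep <- reject_epochs(ep, reject_limit)
  crop_and_baseline(ep, aep_window, baseline)
}
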