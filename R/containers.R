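# Lightweight S3 containers for continuous, epoched and averaged EEG.

#' Construct a continuous EEG recording
#'
#' @param signal Numeric matrix, channels x samples, in microvolts;
#'   rownames are channel names (or supply `channel_names`).
#' @param sr Sampling rate in Hz (> 0).
#' @param events data.frame with at least `onset_sample` (0-based) and
#'   `stim_class` for every stimulus event.
#' @param channel_names Channel names if `signal` has no rownames.
#' @param reference Reference description (`"average"` or a channel name).
#' @param bad_channels Subset of channel names flagged as bad.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(signal, sr, events = NULL, channel_names = NULL,
                          reference = "Cz", bad_channels = character()) {
  if (!is.matrix(signal)) stop("signal must be a channels x samples matrix")
  if (is.null(channel_names)) channel_names <- rownames(signal)
  if (is.null(channel_names)) stop("channel names required")
  stopifnot(length(channel_names) == nrow(signal), sr > 0)
  if (!all(bad_channels %in% channel_names)) {
    stop("bad_channels must be a subset of channel_names")
  }
  rownames(signal) <- channel_names
  structure(
    list(signal = signal, sr = sr, channel_names = channel_names,
         events = events, reference = reference,
         bad_channels = bad_channels),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), ref %s, %d bad, %s events\n",
    nrow(x$signal), ncol(x$signal), x$sr, ncol(x$signal) / x$sr,
    x$reference, length(x$bad_channels),
    if (is.null(x$events)) "no" else nrow(x$events)
  ))
  invisible(x)
}

# Channels retained after bad-channel removal.
retained_channels <- function(rec) {
  setdiff(rec$channel_names, rec$bad_channels)
}

#' Construct a set of stimulus-locked epochs
#'
#' @param data 3-D array `[epoch, channel, time]` in microvolts (or z
#'   units downstream).
#' @param time_ms Time axis in ms relative to stimulus onset; length must
#'   match `dim(data)[3]`.
#' @param stim_class Character vector, one label per epoch.
#' @param channel_names One name per channel.
#' @param keep_mask Logical per epoch (default all TRUE).
#' @param window `[start, end)` window in ms.
#' @return An object of class `epoch_set`.
#' @export
new_epoch_set <- function(data, time_ms, stim_class, channel_names,
                          keep_mask = NULL, window = range(time_ms)) {
  stopifnot(length(dim(data)) == 3L,
            dim(data)[1] == length(stim_class),
            dim(data)[2] == length(channel_names),
            dim(data)[3] == length(time_ms))
  if (is.null(keep_mask)) keep_mask <- rep(TRUE, dim(data)[1])
  stopifnot(length(keep_mask) == dim(data)[1])
  dimnames(data) <- list(NULL, channel_names, NULL)
  structure(
    list(data = data, time_ms = time_ms, stim_class = stim_class,
         channel_names = channel_names, keep_mask = keep_mask,
         window = window),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d epochs (%d kept) x %d channels, %g..%g ms\n",
    length(x$stim_class), sum(x$keep_mask), length(x$channel_names),
    min(x$time_ms), max(x$time_ms)
  ))
  print(table(x$stim_class))
  invisible(x)
}

#' Construct a per-condition average (evoked) waveform
#'
#' @param data Matrix channels x time.
#' @param time_ms Time axis (ms).
#' @param stim_class Condition label (`"S1"`, `"SPrecDev"`, `"Dev"`).
#' @param n_trials Number of trials averaged.
#' @param channel_names One per channel.
#' @param normalized Logical: z units (TRUE) or microvolts (FALSE).
#' @return An object of class `evoked`.
#' @export
new_evoked <- function(data, time_ms, stim_class, n_trials,
                       channel_names = rownames(data), normalized = FALSE) {
  stopifnot(is.matrix(data), ncol(data) == length(time_ms),
            nrow(data) == length(channel_names), n_trials >= 1)
  rownames(data) <- channel_names
  structure(
    list(data = data, time_ms = time_ms, stim_class = stim_class,
         n_trials = n_trials, channel_names = channel_names,
         normalized = normalized),
    class = "evoked"
  )
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf(
    "<evoked> %s: %d channels, %g..%g ms, n = %d%s\n",
    x$stim_class, nrow(x$data), min(x$time_ms), max(x$time_ms),
    x$n_trials, if (x$normalized) " (z units)" else " (uV)"
  ))
  invisible(x)
}
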