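# Condition averaging, per-subject z-normalization, peak extraction and
# the mismatch-negativity difference wave.

#' Average kept epochs by stimulus class
#'
#' @param ep An [new_epoch_set()] (baseline-corrected AEP epochs).
#' @param classes Classes to average; each must have at least one kept
#'   epoch.
#' @return Named list of [new_evoked()] objects.
#' @export
average_by_class <- function(ep, classes = c("S1", "SPrecDev", "Dev")) {
  stopifnot(inherits(ep, "epoch_set"))
  out <- lapply(classes, function(cl) {
    idx <- which(ep$stim_class == cl & ep$keep_mask)
    if (length(idx) == 0L) {
      stop("missing-condition: no kept epochs for class ", cl)
    }
    avg <- apply(ep$data[idx, , , drop = FALSE], c(2, 3), mean)
    new_evoked(avg, ep$time_ms, cl, length(idx),
               channel_names = ep$channel_names, normalized = FALSE)
  })
  names(out) <- classes
  out
}

#' Z-normalize a subject's condition averages
#'
#' Per subject and per channel, one mean and SD are computed over the
#' concatenated S1/SPrecDev/Dev average waveforms (the full AEP window)
#' and `(x - mean)/SD` is applied to each condition. Normalizing with
#' pooled within-subject statistics preserves the within-subject
#' condition contrasts (habituation, change detection) while equating
#' overall scale across subjects and recording systems. The pooled mean
#' and SD are stored in attributes `norm_mean` / `norm_sd` so physical
#' units can be recovered.
#'
#' @param evokeds Named list of [new_evoked()] (all conditions present,
#'   identical channels and time axes).
#' @return The list with each evoked in z units (`normalized = TRUE`).
#' @export
znormalize_subject <- function(evokeds) {
  stopifnot(length(evokeds) >= 1)
  chans <- evokeds[[1]]$channel_names
  cat_dat <- do.call(cbind, lapply(evokeds, function(e) {
    stopifnot(identical(e$channel_names, chans),
              identical(e$time_ms, evokeds[[1]]$time_ms))
    e$data
  }))
  m <- rowMeans(cat_dat)
  s <- apply(cat_dat, 1, stats::sd)
  if (any(s == 0)) stop("degenerate-signal: zero pooled SD on a channel")
  out <- lapply(evokeds, function(e) {
    e$data <- (e$data - m) / s
    e$normalized <- TRUE
    e
  })
  attr(out, "norm_mean") <- stats::setNames(m, chans)
  attr(out, "norm_sd") <- stats::setNames(s, chans)
  out
}

#' Detect a component peak in a latency window
#'
#' Returns the signed extremum of the waveform over the closed window
#' (the most positive value for polarity `"+"`, the most negative for
#' `"-"`) and its latency; latency ties are broken by the earliest
#' sample. No local-maximum requirement is imposed: the window extremum
#' is taken even on a monotone segment.
#'
#' @param wave Numeric waveform (one channel).
#' @param time_ms Time axis, same length as `wave`.
#' @param window `c(lo, hi)` ms, closed at both ends; must lie within
#'   the time axis.
#' @param polarity `"+"` or `"-"`.
#' @return List with `amplitude`, `latency`, `window_used`, `polarity`.
#' @export
detect_peak <- function(wave, time_ms, window, polarity = c("+", "-")) {
  polarity <- match.arg(polarity)
  stopifnot(length(wave) == length(time_ms))
  if (window[1] < min(time_ms) || window[2] > max(time_ms)) {
    stop("invalid-window: window outside the waveform time axis")
  }
  idx <- which(time_ms >= window[1] & time_ms <= window[2])
  seg <- wave[idx]
  k <- if (polarity == "+") which.max(seg) else which.min(seg)
  list(amplitude = seg[k], latency = time_ms[idx[k]],
       window_used = window, polarity = polarity)
}

#' Mismatch-negativity difference wave and peak
#'
#' Subtracts the SPrecDev average from the Dev average pointwise
#' (Dev - SPrecDev) and extracts, per channel, the most negative peak in
#' the window (default 100--350 ms). Computed on normalized evokeds in
#' the pipeline (normalization precedes component extraction).
#'
#' @param dev,sprecdev [new_evoked()] objects on identical time axes
#'   and channels.
#' @param window Peak search window in ms.
#' @return List: `difference` (an evoked labelled `"MMN"`) and `peaks`
#'   (data.frame `channel`, `amplitude`, `latency`).
#' @export
compute_mmn <- function(dev, sprecdev, window = c(100, 350)) {
  if (!identical(dev$time_ms, sprecdev$time_ms) ||
      !identical(dev$channel_names, sprecdev$channel_names)) {
    stop("incompatible-evoked: time axes or channels differ")
  }
  diff_dat <- dev$data - sprecdev$data
  difference <- new_evoked(diff_dat, dev$time_ms, "MMN",
                           min(dev$n_trials, sprecdev$n_trials),
                           channel_names = dev$channel_names,
                           normalized = dev$normalized)
  peaks <- do.call(rbind, lapply(dev$channel_names, function(ch) {
    pk <- detect_peak(diff_dat[ch, ], dev$time_ms, window, "-")
    data.frame(channel = ch, amplitude = pk$amplitude,
               latency = pk$latency, stringsAsFactors = FALSE)
  }))
  list(difference = difference, peaks = peaks)
}

#' Extract the per-subject ERP feature row
#'
#' For each region of interest: P1/N1/P2/N2 amplitude and latency for
#' S1, SPrecDev and Dev; P3a amplitude and latency for SPrecDev and Dev;
#' and the MMN peak from the Dev - SPrecDev difference wave. Habituation
#' contrasts use S1 vs SPrecDev, change detection SPrecDev vs Dev.
#' Features are named `<roi>_<component>_<class>_<amp|lat>` (MMN:
#' `<roi>_MMN_<amp|lat>`). A missing ROI channel leaves its features NA
#' with a warning.
#'
#' @param evokeds Named list with elements `S1`, `SPrecDev`, `Dev`
#'   (normalized).
#' @param rois Channels of interest.
#' @param specs Component table with search windows.
#' @param mmn_window MMN search window in ms.
#' @return One-row data.frame of features.
#' @export
extract_features <- function(evokeds, rois = c("Cz", "FCz"),
                             specs = component_specs(),
                             mmn_window = c(100, 350)) {
  stopifnot(all(c("S1", "SPrecDev", "Dev") %in% names(evokeds)))
  classes_for <- function(comp) {
    if (comp == "P3a") c("SPrecDev", "Dev") else c("S1", "SPrecDev", "Dev")
  }
  row <- list()
  for (roi in rois) {
    have <- roi %in% evokeds$S1$channel_names
    if (!have) warning("ROI channel ", roi, " missing; features set NA")
    for (i in seq_len(nrow(specs))) {
      comp <- specs$name[i]
      pol <- if (specs$polarity[i] > 0) "+" else "-"
      for (cl in classes_for(comp)) {
        key <- paste(roi, comp, cl, sep = "_")
        if (have) {
          ev <- evokeds[[cl]]
          pk <- detect_peak(ev$data[roi, ], ev$time_ms,
                            c(specs$win_lo[i], specs$win_hi[i]), pol)
          row[[paste0(key, "_amp")]] <- pk$amplitude
          row[[paste0(key, "_lat")]] <- pk$latency
        } else {
          row[[paste0(key, "_amp")]] <- NA_real_
          row[[paste0(key, "_lat")]] <- NA_real_
        }
      }
    }
    if (have) {
      mm <- compute_mmn(evokeds$Dev, evokeds$SPrecDev, mmn_window)
      pk <- mm$peaks[mm$peaks$channel == roi, ]
      row[[paste0(roi, "_MMN_amp")]] <- pk$amplitude
      row[[paste0(roi, "_MMN_lat")]] <- pk$latency
    } else {
      row[[paste0(roi, "_MMN_amp")]] <- NA_real_
      row[[paste0(roi, "_MMN_lat")]] <- NA_real_
    }
  }
  as.data.frame(row)
}
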