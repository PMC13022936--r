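#' Generate a passive auditory oddball stimulus sequence
#'
#' Builds the tone sequence of the passive oddball paradigm: trials of
#' repeated 1000 Hz standards ending in a single 2000 Hz deviant, the
#' deviant falling pseudo-randomly at position 5, 6, 7, 8, 9 or 10 of its
#' trial. With the defaults (`reps_per_position = 10`) this yields 450
#' tones: 390 standards (86.67%) and 60 deviants (13.33%). Trial order is
#' a seeded uniform permutation of the multiset `{5..10} x reps`.
#'
#' Tones are 70 ms long (10 ms rise/fall included); consecutive onsets are
#' spaced by `soa_ms` (70 ms tone + 1000 ms silent interval by default, the
#' inter-trial interval being identical to the interstimulus interval).
#'
#' @param seed Integer seed; identical seeds give identical sessions.
#' @param reps_per_position Number of trials per deviant position (>= 1).
#' @param soa_ms Onset-to-onset interval in ms (> 70).
#' @param tone_ms Tone duration in ms.
#' @param standard_hz,deviant_hz Tone frequencies in Hz.
#' @return An object of class `oddball_session`: a data.frame of tone
#'   events with columns `onset` (ms from session start), `frequency`,
#'   `duration`, `role` (`"standard"`/`"deviant"`), `trial_index`
#'   (0-based), `position_in_trial` (1-based) and `stim_class`
#'   (`"S1"`, `"SPrecDev"`, `"Dev"`, `"other_standard"`), with attributes
#'   `soa`, `seed`, `reps_per_position`.
#' @examples
#' s <- generate_session(seed = 1)
#' session_counts(s)
#' @export
generate_session <- function(seed = 1L, reps_per_position = 10L,
                             soa_ms = 1070, tone_ms = 70,
                             standard_hz = 1000, deviant_hz = 2000) {
  if (!is.numeric(reps_per_position) || reps_per_position < 1) {
    stop("invalid-config: reps_per_position must be >= 1")
  }
  if (soa_ms <= tone_ms) {
    stop("invalid-config: soa_ms must exceed the tone duration")
  }
  reps_per_position <- as.integer(reps_per_position)
  positions <- rep(5:10, each = reps_per_position)
  order <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    sample(positions)
  })

  trial_index <- rep(seq_along(order) - 1L, times = order)
  position_in_trial <- unlist(lapply(order, seq_len), use.names = FALSE)
  n <- length(trial_index)
  is_dev <- position_in_trial == rep(order, times = order)
  events <- data.frame(
    onset = (seq_len(n) - 1) * soa_ms,
    frequency = ifelse(is_dev, deviant_hz, standard_hz),
    duration = tone_ms,
    role = ifelse(is_dev, "deviant", "standard"),
    trial_index = trial_index,
    position_in_trial = position_in_trial,
    stim_class = NA_character_,
    stringsAsFactors = FALSE
  )
  session <- structure(events,
    class = c("oddball_session", "data.frame"),
    soa = soa_ms, seed = as.integer(seed),
    reps_per_position = reps_per_position
  )
  label_stimulus_classes(session)
}

#' Label S1, SPrecDev and Dev stimulus classes
#'
#' Assigns each tone its analysis class: the first standard of every trial
#' is `S1`, the standard immediately preceding the deviant is `SPrecDev`,
#' the deviant itself `Dev`, and all remaining standards
#' `other_standard`. Labeling is idempotent.
#'
#' @param session An `oddball_session` (every trial must end with its
#'   deviant).
#' @return The session with `stim_class` filled in.
#' @export
label_stimulus_classes <- function(session) {
  stopifnot(inherits(session, "oddball_session"))
  cls <- rep("other_standard", nrow(session))
  for (tr in unique(session$trial_index)) {
    idx <- which(session$trial_index == tr)
    roles <- session$role[idx]
    if (roles[length(idx)] != "deviant" || sum(roles == "deviant") != 1L) {
      stop("malformed-session: each trial must contain exactly one final deviant")
    }
    cls[idx[1L]] <- "S1"
    cls[idx[length(idx) - 1L]] <- "SPrecDev"
    cls[idx[length(idx)]] <- "Dev"
  }
  session$stim_class <- cls
  session
}

#' Count tones and class percentages in a session
#'
#' @param session An `oddball_session`.
#' @return A list with `n_total`, `n_standard`, `n_deviant`,
#'   `pct_standard`, `pct_deviant` (percentages rounded to 2 decimals).
#' @export
session_counts <- function(session) {
  stopifnot(inherits(session, "oddball_session"))
  if (nrow(session) == 0L) stop("empty-input: session has no events")
  n <- nrow(session)
  nd <- sum(session$role == "deviant")
  list(
    n_total = n,
    n_standard = n - nd,
    n_deviant = nd,
    pct_standard = round(100 * (n - nd) / n, 2),
    pct_deviant = round(100 * nd / n, 2)
  )
}

#' @export
print.oddball_session <- function(x, ...) {
  cnt <- session_counts(x)
  cat(sprintf(
    "<oddball_session> %d tones (%d standard / %d deviant), SOA %g ms, seed %d\n",
    cnt$n_total, cnt$n_standard, cnt$n_deviant,
    attr(x, "soa"), attr(x, "seed")
  ))
  invisible(x)
}

#' Write or read a session event table (TSV)
#'
#' The on-disk event format is tab-separated with a header row and columns
#' `onset_sample` (0-based at `sr` Hz), `frequency_hz`, `role`,
#' `trial_index`, `position_in_trial`, `stim_class`.
#'
#' @param session An `oddball_session`.
#' @param path Output file.
#' @param sr Sampling rate (Hz) used to convert onset ms to samples.
#' @return `write_session_tsv` returns `path` invisibly; `read_session_tsv`
#'   returns an `oddball_session`.
#' @export
write_session_tsv <- function(session, path, sr = 1000) {
  stopifnot(inherits(session, "oddball_session"))
  out <- data.frame(
    onset_sample = as.integer(round(session$onset * sr / 1000)),
    frequency_hz = session$frequency,
    role = session$role,
    trial_index = session$trial_index,
    position_in_trial = session$position_in_trial,
    stim_class = session$stim_class
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_tsv
#' @param soa_ms,seed,reps_per_position Session attributes to restore
#'   (not stored in the TSV).
#' @export
read_session_tsv <- function(path, sr = 1000, soa_ms = NULL, seed = NA_integer_,
                             reps_per_position = NA_integer_) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  onset <- tab$onset_sample * 1000 / sr
  if (is.null(soa_ms)) {
    soa_ms <- if (nrow(tab) > 1L) diff(onset)[1L] else NA_real_
  }
  structure(
    data.frame(
      onset = onset,
      frequency = tab$frequency_hz,
      duration = 70,
      role = tab$role,
      trial_index = tab$trial_index,
      position_in_trial = tab$position_in_trial,
      stim_class = tab$stim_class,
      stringsAsFactors = FALSE
    ),
    class = c("oddball_session", "data.frame"),
    soa = soa_ms, seed = as.integer(seed),
    reps_per_position = as.integer(reps_per_position)
  )
}
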