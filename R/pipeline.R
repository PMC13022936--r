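# End-to-end orchestration: simulate -> (preprocess) -> ERP features ->
# inference, with one master seed driving every stage.

#' Build a run configuration
#'
#' All thresholds default to the analysis values: 0.5--150 Hz band-pass
#' with 60 Hz notch, bad channels at SD < 2 / > 120 uV, +/- 200 uV epoch
#' rejection, -200..600 ms AEP window with -200..0 ms baseline, ROIs Cz
#' and FCz, 5% FDR. `mode = "evoked"` simulates per-condition averages
#' directly (fast path, exact for averaged stationary noise);
#' `mode = "recording"` synthesizes the continuous EEG and runs the full
#' preprocessing chain.
#'
#' @param seed Master seed; every per-subject seed derives from it.
#' @param n_clinical,n_control Cohort sizes.
#' @param mode `"evoked"` or `"recording"`.
#' @param n_trials Trials per stimulus class in evoked mode.
#' @param reps_per_position,soa_ms Paradigm parameters.
#' @param effects,noise,score_model Generator configuration.
#' @param rois Regions of interest.
#' @param q FDR level for the correlation screen.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_clinical = 41, n_control = 46,
                       mode = c("evoked", "recording"), n_trials = 60,
                       reps_per_position = 10, soa_ms = 1070,
                       effects = effect_config(), noise = noise_spec(),
                       score_model = score_model_null(),
                       rois = c("Cz", "FCz"), q = 0.05) {
  mode <- match.arg(mode)
  structure(
    list(seed = seed, n_clinical = n_clinical, n_control = n_control,
         mode = mode, n_trials = n_trials,
         reps_per_position = reps_per_position, soa_ms = soa_ms,
         specs = component_specs(), effects = effects, noise = noise,
         score_model = score_model, rois = rois, q = q,
         hp = 0.5, lp = 150, notch = 60, sd_lo = 2, sd_hi = 120,
         reject_limit = 200, aep_window = c(-200, 600),
         baseline = c(-200, 0), mmn_window = c(100, 350)),
    class = "run_config"
  )
}

#' Serialize / restore a run configuration (YAML)
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  to_plain <- function(x) {
    if (is.data.frame(x)) {
      lapply(as.list(x), to_plain)
    } else if (is.list(x)) {
      lapply(unclass(x), to_plain)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)  # named vectors serialize as maps, keeping names
    } else {
      x
    }
  }
  yaml::write_yaml(lapply(unclass(config), to_plain), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  ints <- c("seed", "n_clinical", "n_control", "n_trials",
            "reps_per_position")
  for (nm in names(raw)) {
    val <- raw[[nm]]
    cfg[[nm]] <- switch(nm,
      specs = as.data.frame(lapply(val, unlist), stringsAsFactors = FALSE),
      score_model = as.data.frame(lapply(val, unlist),
                                  stringsAsFactors = FALSE),
      effects = do.call(effect_config, lapply(val, function(v) {
        if (is.list(v)) unlist(v) else v
      })),
      noise = do.call(noise_spec, val),
      {
        out <- if (is.list(val)) unlist(val) else val
        if (nm %in% ints) as.integer(out) else out
      }
    )
  }
  cfg
}

# Features for one subject row, by the configured simulation path.
subject_features <- function(subject, config) {
  if (config$mode == "evoked") {
    ev <- simulate_evoked(subject, n_trials = config$n_trials,
                          specs = config$specs, effects = config$effects,
                          noise = config$noise, channels = config$rois,
                          seed = subject$seed)
  } else {
    session <- generate_session(seed = subject$seed,
                                reps_per_position = config$reps_per_position,
                                soa_ms = config$soa_ms)
    rec <- simulate_recording(subject, session, specs = config$specs,
                              effects = config$effects, noise = config$noise,
                              seed = subject$seed, keep_truth = FALSE)
    ep <- preprocess_recording(rec, hp = config$hp, lp = config$lp,
                               notch = config$notch, sd_lo = config$sd_lo,
                               sd_hi = config$sd_hi,
                               reject_limit = config$reject_limit,
                               aep_window = config$aep_window,
                               baseline = config$baseline)
    ev <- average_by_class(ep)
    ev <- lapply(ev, function(e) {
      keep <- intersect(config$rois, e$channel_names)
      new_evoked(e$data[keep, , drop = FALSE], e$time_ms, e$stim_class,
                 e$n_trials, channel_names = keep)
    })
  }
  evn <- znormalize_subject(ev)
  list(features = extract_features(evn, rois = config$rois,
                                   specs = config$specs,
                                   mmn_window = config$mmn_window),
       evokeds = evn)
}

#' Simulate a cohort and extract its ERP feature table
#'
#' Runs the simulation and feature-extraction stages of the pipeline:
#' cohort generation, per-subject evoked responses (or full recordings,
#' depending on `config$mode`), z-normalization and peak extraction.
#'
#' @param config A [run_config()].
#' @return List: `cohort` (subjects with latents and scores), `features`
#'   (id/group/age/sex + the feature grid + scores), `grand_avg`
#'   (long data.frame of group x condition mean waveforms at the ROIs).
#' @export
cohort_features <- function(config = run_config()) {
  cohort <- simulate_cohort(config$n_clinical, config$n_control,
                            specs = config$specs, effects = config$effects,
                            score_model = config$score_model,
                            seed = config$seed)
  feats <- vector("list", nrow(cohort))
  gsum <- list()
  for (i in seq_len(nrow(cohort))) {
    sf <- subject_features(cohort[i, ], config)
    feats[[i]] <- sf$features
    g <- cohort$group[i]
    for (cl in names(sf$evokeds)) {
      key <- paste(g, cl, sep = ".")
      dat <- sf$evokeds[[cl]]$data
      gsum[[key]] <- if (is.null(gsum[[key]])) dat else gsum[[key]] + dat
    }
  }
  features <- cbind(cohort[, c("id", "group", "age", "sex")],
                    do.call(rbind, feats))
  scores <- setdiff(unique(config$score_model$score), names(features))
  features <- cbind(features, cohort[, scores, drop = FALSE])

  n_by_group <- table(cohort$group)
  grand_avg <- do.call(rbind, lapply(names(gsum), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    avg <- gsum[[key]] / n_by_group[[parts[1]]]
    do.call(rbind, lapply(rownames(avg), function(ch) {
      data.frame(group = parts[1], stim_class = parts[2], channel = ch,
                 time_ms = aep_time(), value = avg[ch, ],
                 stringsAsFactors = FALSE)
    }))
  }))
  list(cohort = cohort, features = features, grand_avg = grand_avg)
}

#' Run the full pipeline on a simulated cohort
#'
#' Simulates the cohort, derives per-subject features, runs the
#' habituation (S1 vs SPrecDev) and change-detection (SPrecDev vs Dev)
#' mixed ANOVAs with the age covariate for every component, measure and
#' ROI, the MMN one-way ANCOVA, and the clinical correlation screen on
#' the clinical group. When `outdir` is given, writes `features.csv`,
#' `anova.csv`, `correlations.csv` and `run.json` (identical config and
#' seed give byte-identical CSVs).
#'
#' @param config A [run_config()].
#' @param outdir Output directory (NULL for no files).
#' @return List: `cohort`, `features`, `anovas`, `correlations`,
#'   `grand_avg` (per group/condition ROI waveforms), `run_info`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  if (config$n_clinical < 5 || config$n_control < 5) {
    warning("very small groups (n < 5); inference will be unstable")
  }
  cf <- cohort_features(config)
  cohort <- cf$cohort
  features <- cf$features
  grand_avg <- cf$grand_avg

  anovas <- pipeline_anovas(features, config)
  clin <- features[features$group == "clinical", , drop = FALSE]
  pairs <- default_screen_pairs(rois = config$rois)
  pairs <- pairs[pairs$score %in% names(features), , drop = FALSE]
  correlations <- correlation_screen(clin, pairs, q = config$q)

  run_info <- list(
    package_version = as.character(utils::packageVersion("oddballAEP")),
    master_seed = config$seed,
    subject_seeds = stats::setNames(cohort$seed, cohort$id),
    mode = config$mode,
    n_clinical = config$n_clinical, n_control = config$n_control,
    n_features = ncol(features),
    n_flagged_correlations = sum(correlations$fdr_flag)
  )
  out <- list(cohort = cohort, features = features, anovas = anovas,
              correlations = correlations, grand_avg = grand_avg,
              run_info = run_info, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(features, file.path(outdir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(anovas, file.path(outdir, "anova.csv"),
                     row.names = FALSE)
    utils::write.csv(correlations, file.path(outdir, "correlations.csv"),
                     row.names = FALSE)
    jsonlite::write_json(run_info, file.path(outdir, "run.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    out$paths <- file.path(outdir, c("features.csv", "anova.csv",
                                     "correlations.csv", "run.json"))
  }
  out
}

# The ANOVA grid: habituation and change detection per component,
# measure and ROI, plus the MMN ANCOVA.
pipeline_anovas <- function(features, config) {
  rows <- list()
  add <- function(analysis, roi, comp, meas, res) {
    rows[[length(rows) + 1]] <<- cbind(
      data.frame(analysis = analysis, roi = roi, component = comp,
                 measure = meas, n = res$n, stringsAsFactors = FALSE),
      res$anova
    )
  }
  for (roi in config$rois) {
    for (meas in c("amp", "lat")) {
      for (comp in c("P1", "N1", "P2", "N2")) {
        a <- paste(roi, comp, "S1", meas, sep = "_")
        b <- paste(roi, comp, "SPrecDev", meas, sep = "_")
        res <- mixed_anova_covariate(features, a, b)
        add("habituation", roi, comp, meas, res)
      }
      for (comp in c("P1", "N1", "P2", "N2", "P3a")) {
        a <- paste(roi, comp, "SPrecDev", meas, sep = "_")
        b <- paste(roi, comp, "Dev", meas, sep = "_")
        res <- mixed_anova_covariate(features, a, b)
        add("change_detection", roi, comp, meas, res)
      }
      res <- ancova_oneway(features, paste(roi, "MMN", meas, sep = "_"))
      add("mmn", roi, "MMN", meas, res)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a human-readable run report
#'
#' Grand-average waveform plots per group and condition at the ROIs
#' (habituation panel: S1 vs SPrecDev; change-detection panel: SPrecDev
#' vs Dev), the ANOVA table, and the FDR-flagged correlations. When
#' `outdir` is given a markdown summary is written.
#'
#' @param run Output of [run_pipeline()].
#' @param outdir Directory for `report.md` (NULL to skip writing).
#' @return List: `plots` (named ggplot objects), `summary_lines`,
#'   `flagged` (significant correlations; may have zero rows).
#' @export
make_report <- function(run, outdir = NULL) {
  if (is.null(run$grand_avg)) stop("missing outputs: no grand averages")
  ga <- run$grand_avg
  plot_panel <- function(classes, title) {
    d <- ga[ga$stim_class %in% classes, ]
    ggplot2::ggplot(d, ggplot2::aes(x = time_ms, y = value,
                                    colour = group,
                                    linetype = stim_class)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~channel) +
      ggplot2::labs(title = title, x = "time (ms)", y = "amplitude (z)")
  }
  plots <- list(
    habituation = plot_panel(c("S1", "SPrecDev"),
                             "Grand averages: S1 vs SPrecDev"),
    change_detection = plot_panel(c("SPrecDev", "Dev"),
                                  "Grand averages: SPrecDev vs Dev")
  )
  flagged <- run$correlations[run$correlations$fdr_flag, , drop = FALSE]
  sig <- run$anovas[run$anovas$p < 0.05, , drop = FALSE]
  lines <- c(
    "# Oddball AEP run report",
    "",
    sprintf("Cohort: %d clinical / %d control (seed %s, mode %s).",
            run$run_info$n_clinical, run$run_info$n_control,
            run$run_info$master_seed, run$run_info$mode),
    "",
    sprintf("ANOVA effects with p < .05: %d of %d.", nrow(sig),
            nrow(run$anovas)),
    "",
    if (nrow(flagged) == 0) {
      "No significant correlations survived FDR correction."
    } else {
      c("FDR-flagged correlations:",
        sprintf("- %s ~ %s (%s): r = %.2f, p = %.4f", flagged$feature,
                flagged$score, flagged$covariates, flagged$r, flagged$p))
    }
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeLines(lines, file.path(outdir, "report.md"))
  }
  list(plots = plots, summary_lines = lines, flagged = flagged)
}
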