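#' Simulate a two-group cohort with latent ERP parameters
#'
#' Draws demographics matching the study population shape (clinical group:
#' ages ~17 +/- 8 truncated to 7--34, ~76% male; control group: ages
#' ~15 +/- 10 truncated to 5--30, ~46% male) and, per subject, latent
#' component amplitudes (uV, S1 magnitude) and latencies (ms) that apply
#' the group ratios, latency shift and age slopes of the
#' [effect_config()]. These latents are the ground truth every downstream
#' stage is tested against.
#'
#' @param n_clinical,n_control Group sizes (>= 2 each).
#' @param specs Component specification table ([component_specs()]).
#' @param effects An [effect_config()].
#' @param seed Integer seed.
#' @return A data.frame, one row per subject: `id`, `group`
#'   (`"clinical"`/`"control"`), `age`, `sex` (`"M"`/`"F"`), `seed`
#'   (per-subject derived seed), plus latent columns `amp_<comp>` and
#'   `lat_<comp>`.
#' @export
simulate_subjects <- function(n_clinical = 41, n_control = 46,
                              specs = component_specs(),
                              effects = effect_config(), seed = 1) {
  if (n_clinical < 2 || n_control < 2) {
    stop("invalid-config: at least 2 subjects per group")
  }
  with_seed(seed, {
    n <- n_clinical + n_control
    group <- rep(c("clinical", "control"), c(n_clinical, n_control))
    age <- ifelse(group == "clinical",
      rtrunc_norm(n, 16.95, 7.75, 7, 34),
      rtrunc_norm(n, 15.00, 9.69, 5, 30)
    )
    p_male <- ifelse(group == "clinical", 31 / 41, 21 / 46)
    sex <- ifelse(stats::runif(n) < p_male, "M", "F")
    sub <- data.frame(
      id = sprintf("S%03d", seq_len(n)),
      group = group, age = age, sex = sex,
      seed = derive_seed(seed, seq_len(n)),
      stringsAsFactors = FALSE
    )
    for (i in seq_len(nrow(specs))) {
      comp <- specs$name[i]
      ratio <- ifelse(group == "clinical",
                      effects$group_amp_ratio[[comp]], 1)
      amp <- specs$amplitude_mean[i] * ratio +
        effects$age_amp_slope[[comp]] * (age - effects$age_ref) +
        stats::rnorm(n, 0, specs$amplitude_sd[i])
      shift <- ifelse(group == "clinical", effects$group_latency_shift, 0)
      lat <- specs$latency_mean[i] + shift +
        stats::rnorm(n, 0, specs$latency_sd[i])
      sub[[paste0("amp_", comp)]] <- pmax(amp, 0.05)
      sub[[paste0("lat_", comp)]] <- pmin(pmax(lat, specs$win_lo[i] + 5),
                                          specs$win_hi[i] - 5)
    }
    sub
  })
}

# Truncated-normal draw by rejection (bounds are a few SD wide, so the
# acceptance rate is high).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Default clinical-score model (global null)
#'
#' One row per (latent feature, score) pair with a target partial
#' correlation `r` (controlling sex, and age for the instruments without
#' age-based norms). The default targets r = 0 everywhere: scores are
#' pure noise, the regime under which the correlation screen's
#' false-discovery control is assessed. Score direction conventions:
#' higher `nviq`/`adaptive` is better, higher `asd_severity`,
#' `social_avoidance`, `depressed_mood`, `adhd` is worse.
#'
#' @param r Target partial correlation applied to every default pair.
#' @return data.frame with columns `feature`, `score`, `r`.
#' @export
score_model_null <- function(r = 0) {
  data.frame(
    feature = c("lat_P1", "amp_P2", "amp_N1", "amp_N2", "amp_N2", "amp_P2"),
    score = c("nviq", "asd_severity", "adaptive", "social_avoidance",
              "depressed_mood", "adhd"),
    r = r,
    stringsAsFactors = FALSE
  )
}

#' Attach clinical scores with calibrated partial correlations
#'
#' Each score is a linear function of the (within-group, covariate-
#' residualized, standardized) latent feature named in `score_model` plus
#' Gaussian noise, mixed so the population partial correlation
#' (controlling sex, and age where `age_covariate` says so) equals the
#' target `r`. Scores are then rescaled to conventional means/SDs
#' (NVIQ-like 50 +/- 15, others 10 +/- 3).
#'
#' @param subjects Output of [simulate_subjects()].
#' @param score_model data.frame `feature`, `score`, `r`; at most one
#'   feature per score.
#' @param age_covariate Named logical per score: control for age when
#'   residualizing (defaults to TRUE for every score, matching
#'   instruments without age-based norms; NVIQ and adaptive scales are
#'   age-normed, so age is excluded for them).
#' @param seed Integer seed.
#' @return `subjects` with one numeric column per score.
#' @export
attach_scores <- function(subjects, score_model = score_model_null(),
                          age_covariate = NULL, seed = 1) {
  stopifnot(all(c("feature", "score", "r") %in% names(score_model)))
  if (any(abs(score_model$r) >= 1)) {
    stop("invalid-config: target |r| must be < 1")
  }
  if (any(duplicated(score_model$score))) {
    stop("invalid-config: one latent feature per score")
  }
  defaults <- c(nviq = FALSE, adaptive = FALSE)
  with_seed(seed, {
    for (j in seq_len(nrow(score_model))) {
      feat <- score_model$feature[j]
      sc <- score_model$score[j]
      r <- score_model$r[j]
      if (!feat %in% names(subjects)) {
        stop("invalid-config: unknown latent feature ", feat)
      }
      use_age <- if (!is.null(age_covariate) && sc %in% names(age_covariate)) {
        isTRUE(age_covariate[[sc]])
      } else if (sc %in% names(defaults)) {
        defaults[[sc]]
      } else {
        TRUE
      }
      z <- rep(NA_real_, nrow(subjects))
      for (g in unique(subjects$group)) {
        idx <- which(subjects$group == g)
        dat <- subjects[idx, , drop = FALSE]
        Z <- cbind(1, as.numeric(factor(dat$sex)),
                   if (use_age) dat$age)
        # constant covariate columns (e.g. single-sex group) drop out
        Z <- Z[, c(TRUE, apply(Z[, -1, drop = FALSE], 2, stats::sd) > 0),
               drop = FALSE]
        res <- stats::lm.fit(Z, dat[[feat]])$residuals
        s <- stats::sd(res)
        z[idx] <- if (s > 0) res / s else 0
      }
      raw <- r * z + sqrt(1 - r^2) * stats::rnorm(nrow(subjects))
      subjects[[sc]] <- if (sc == "nviq") 50 + 15 * raw else 10 + 3 * raw
    }
    subjects
  })
}

#' Simulate a full cohort: demographics, latent ERP parameters, scores
#'
#' Convenience wrapper around [simulate_subjects()] and
#' [attach_scores()]. Continuous recordings are generated on demand per
#' subject with [simulate_recording()] (each subject row carries its
#' derived seed), so large cohorts stay cheap when only features are
#' needed.
#'
#' @inheritParams simulate_subjects
#' @inheritParams attach_scores
#' @return data.frame of subjects with latents and scores.
#' @examples
#' coh <- simulate_cohort(n_clinical = 5, n_control = 5, seed = 2)
#' table(coh$group)
#' @export
simulate_cohort <- function(n_clinical = 41, n_control = 46,
                            specs = component_specs(),
                            effects = effect_config(),
                            score_model = score_model_null(),
                            age_covariate = NULL, seed = 1) {
  sub <- simulate_subjects(n_clinical, n_control, specs, effects, seed)
  attach_scores(sub, score_model, age_covariate,
                seed = derive_seed(seed, 999983))
}

#' Write a cohort table as CSV
#'
#' @param subjects Cohort data.frame.
#' @param path Output file.
#' @export
write_cohort_csv <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}
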