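# Shared fixture builders and caches for the suite.

# A small deterministic cohort used by several files.
tiny_cohort <- function(seed = 3) {
  simulate_cohort(n_clinical = 6, n_control = 6, seed = seed)
}

# Effect configuration with every group/condition contrast switched off
# (the global null used for type-I checks).
null_effects <- function() {
  effect_config(
    group_amp_ratio = c(P1 = 1, N1 = 1, P2 = 1, N2 = 1, P3a = 1),
    group_latency_shift = 0,
    habituation_factor = c(clinical = 1, control = 1),
    deviance_boost = c(clinical = 1, control = 1),
    mmn_extra = c(clinical = 1, control = 1)
  )
}

# One parameter-recovery replicate at the study conditions (30 subjects
# per group, 60 trials per class): simulate a cohort, extract features
# at Cz/FCz, and return the habituation mixed-ANOVA p values for N1
# amplitude (S1 vs SPrecDev).
recovery_rep <- function(seed, effects) {
  coh <- simulate_cohort(30, 30, effects = effects, seed = seed)
  feats <- do.call(rbind, lapply(seq_len(nrow(coh)), function(i) {
    ev <- simulate_evoked(coh[i, ], n_trials = 60, effects = effects,
                          seed = coh$seed[i])
    extract_features(znormalize_subject(ev))
  }))
  tab <- cbind(coh[, c("group", "age")], feats)
  res <- mixed_anova_covariate(tab, "Cz_N1_S1_amp", "Cz_N1_SPrecDev_amp")
  a <- res$anova
  c(interaction_p = a$p[a$effect == "within:group"],
    group_p = a$p[a$effect == "group"])
}

# Cache shared by the acceptance blocks so the expensive replicate sets
# are simulated once per test run.
acceptance_cache <- new.env(parent = emptyenv())

recovery_replicates <- function(n_reps = 100, base_seed = 20000) {
  key <- paste0("alt_", n_reps, "_", base_seed)
  if (is.null(acceptance_cache[[key]])) {
    acceptance_cache[[key]] <- vapply(
      seq_len(n_reps),
      function(i) recovery_rep(base_seed + i, effect_config()),
      c(interaction_p = 0, group_p = 0)
    )
  }
  acceptance_cache[[key]]
}
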