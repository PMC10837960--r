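# Shared fixtures built in code.

ref_os <- als_reference_params("OS")
ref_emax <- als_reference_params("ALSFRS")

# A tiny deterministic three-arm corpus lying exactly on the reference
# curves (no random effects, no noise).
tiny_corpus <- function(ns = c(11L, 75L, 468L)) {
  arms <- lapply(seq_along(ns), function(i) {
    cv <- covariate_profile(duration_months = c(12, 17.8, 30)[i],
                            riluzole_frac = c(0, 0.9, 1)[i],
                            age_onset_years = 55 + i,
                            male_frac = 0.6,
                            pub_year = 2000L + i)
    tt <- c(6, 12, 24)
    study_arm(sprintf("S%d", i), ns[i], cv,
              os_series = data.frame(
                time_months = tt,
                surv_prob = os_survival(tt, cv, ref_os)),
              score_series = data.frame(
                time_months = tt,
                mean_change = typical_change(tt, ref_emax)))
  })
  als_corpus(arms)
}

# quiet generator wrappers used across tests
quiet_fit <- function(...) suppressMessages(suppressWarnings(mbma_fit(...)))

small_config <- function(n_os_arms = 12L, n_score_arms = 12L, ...,
                         seed = NULL) {
  generator_config(n_os_arms = n_os_arms, n_score_arms = n_score_arms,
                   os_grid = seq(6, 48, by = 6), seed = seed, ...)
}
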