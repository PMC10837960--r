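#' Configuration of the synthetic-corpus generator
#'
#' Defines the study conditions the generator emulates: the corpus
#' composition (30 OS arms, 29 ALSFRS-R arms), a log-uniform arm-size
#' distribution over 11--468 (median about 75), covariate distributions
#' spanning the published corpus ranges, 3-monthly observation grids,
#' and the published final-model parameters as the generating truth.
#'
#' @param n_os_arms,n_score_arms Numbers of arms per endpoint.
#' @param n_range Arm-size range (log-uniform).
#' @param duration_range Disease duration range, months (uniform).
#' @param riluzole_mix Riluzole-proportion mixture: with probability
#'   `p_high` uniform on `high`, else uniform on `low` (mass near 0.9,
#'   support \[0, 1\]).
#' @param age_range,male_range,bulbar_range,baseline_range Uniform
#'   ranges for the optional covariates.
#' @param pub_years Publication years sampled uniformly.
#' @param p_basic Probability of the basic-treatment flag.
#' @param os_grid OS observation times, months.
#' @param score_t_step Score observation spacing, months.
#' @param score_max_choices Arm-level follow-up horizons for the score
#'   series (sampled uniformly).
#' @param os_params,emax_params Generating parameters (defaults: the
#'   published final models, [als_reference_params()]).
#' @param monotonize Apply a cumulative-minimum projection to noisy
#'   survival series (mimicking digitized Kaplan-Meier data); set
#'   `FALSE` for raw likelihood-level noise.
#' @param seed Default seed used by [generate_corpus()].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_os_arms = 30L, n_score_arms = 29L,
                             n_range = c(11L, 468L),
                             duration_range = c(9, 36),
                             riluzole_mix = list(p_high = 0.75,
                                                 high = c(0.8, 1),
                                                 low = c(0, 0.8)),
                             age_range = c(51, 65),
                             male_range = c(0.45, 0.72),
                             bulbar_range = c(0.1, 0.4),
                             baseline_range = c(31, 43),
                             pub_years = 1994:2022,
                             p_basic = 0.5,
                             os_grid = seq(3, 60, by = 3),
                             score_t_step = 3,
                             score_max_choices = seq(3, 48, by = 3),
                             os_params = als_reference_params("OS"),
                             emax_params = als_reference_params("ALSFRS"),
                             monotonize = TRUE, seed = NULL) {
  stopifnot(n_range[1L] >= 11L, n_range[2L] >= n_range[1L])
  structure(list(n_os_arms = n_os_arms, n_score_arms = n_score_arms,
                 n_range = n_range, duration_range = duration_range,
                 riluzole_mix = riluzole_mix, age_range = age_range,
                 male_range = male_range, bulbar_range = bulbar_range,
                 baseline_range = baseline_range, pub_years = pub_years,
                 p_basic = p_basic, os_grid = os_grid,
                 score_t_step = score_t_step,
                 score_max_choices = score_max_choices,
                 os_params = os_params, emax_params = emax_params,
                 monotonize = monotonize, seed = seed),
            class = "generator_config")
}

#' Read a generator configuration from YAML
#'
#' Scalar fields of [generator_config()] may be overridden from a YAML
#' file; model parameters stay at the published defaults unless given
#' as nested blocks with the [os_params()]/[emax_params()] argument
#' names.
#'
#' @param path YAML file path.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  scalar_fields <- c("n_os_arms", "n_score_arms", "n_range",
                     "duration_range", "age_range", "male_range",
                     "bulbar_range", "baseline_range", "pub_years",
                     "p_basic", "os_grid", "score_t_step",
                     "score_max_choices", "monotonize", "seed")
  for (f in intersect(scalar_fields, names(y))) args[[f]] <- y[[f]]
  if (!is.null(y$os_params)) args$os_params <- do.call(os_params, y$os_params)
  if (!is.null(y$emax_params))
    args$emax_params <- do.call(emax_params, y$emax_params)
  do.call(generator_config, args)
}

draw_covariates <- function(config) {
  rmix <- config$riluzole_mix
  ril <- if (stats::runif(1) < rmix$p_high)
    stats::runif(1, rmix$high[1L], rmix$high[2L])
  else stats::runif(1, rmix$low[1L], rmix$low[2L])
  covariate_profile(
    duration_months = stats::runif(1, config$duration_range[1L],
                                   config$duration_range[2L]),
    riluzole_frac = ril,
    age_onset_years = stats::runif(1, config$age_range[1L],
                                   config$age_range[2L]),
    male_frac = stats::runif(1, config$male_range[1L],
                             config$male_range[2L]),
    bulbar_frac = stats::runif(1, config$bulbar_range[1L],
                               config$bulbar_range[2L]),
    baseline_alsfrs = stats::runif(1, config$baseline_range[1L],
                                   config$baseline_range[2L]),
    basic_treatment = as.numeric(stats::runif(1) < config$p_basic),
    pub_year = sample(config$pub_years, 1L))
}

draw_arm_size <- function(config) {
  n <- round(exp(stats::runif(1, log(config$n_range[1L]),
                              log(config$n_range[2L]))))
  max(config$n_range[1L], min(config$n_range[2L], n))
}

gen_os_arm <- function(id, config, effect = 1) {
  p <- config$os_params
  cv <- draw_covariates(config)
  n <- draw_arm_size(config)
  eta <- stats::rnorm(length(p$eta_sd), 0, p$eta_sd)
  tt <- config$os_grid
  s <- os_survival(tt, cv, p, eta)^effect
  y <- link_surv(clip_surv(s), p$obs_scale) +
    stats::rnorm(length(tt), 0, p$eps_sd * sqrt(MEDIAN_ARM_N / n))
  s_obs <- clip_surv(unlink_surv(y, p$obs_scale), 1e-6, 1 - 1e-6)
  if (config$monotonize) s_obs <- cummin(s_obs)
  study_arm(id, n, cv,
            os_series = data.frame(time_months = tt, surv_prob = s_obs),
            strict = config$monotonize)
}

gen_score_arm <- function(id, config, effect = 1) {
  p <- config$emax_params
  cv <- draw_covariates(config)
  n <- draw_arm_size(config)
  eta <- stats::rnorm(2L, 0, p$eta_sd)
  tmax <- sample(config$score_max_choices, 1L)
  tt <- seq(config$score_t_step, tmax, by = config$score_t_step)
  p_eff <- p
  p_eff$emax <- min(p$emax * effect, 48)
  p_eff$base[["emax"]] <- p_eff$emax
  ch <- typical_change(tt, p_eff, eta) +
    stats::rnorm(length(tt), 0, p$eps_sd * sqrt(MEDIAN_ARM_N / n))
  ch <- pmax(pmin(ch, 48), -48)
  study_arm(id, n, cv,
            score_series = data.frame(time_months = tt, mean_change = ch))
}

#' Generate a synthetic aggregate corpus
#'
#' Draws arms under the configured study conditions: covariates and
#' sizes per arm, study-level random effects (multiplicative
#' lognormal), structural curves from the OS and sigmoid-Emax models,
#' and size-weighted residual noise on the configured observation
#' scale. Survival series are clipped to (0, 1) and, by default,
#' projected to be non-increasing (as digitized Kaplan-Meier data are).
#'
#' @param config A [generator_config()].
#' @param seed Seed (defaults to `config$seed`); the same seed
#'   reproduces the corpus exactly.
#' @return An [als_corpus()].
#' @export
#' @examples
#' corpus <- generate_corpus(generator_config(seed = 1))
#' summarize_corpus(corpus)[1:3, ]
generate_corpus <- function(config = generator_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  arms <- c(
    lapply(seq_len(config$n_os_arms), function(i)
      gen_os_arm(sprintf("OS%02d", i), config)),
    lapply(seq_len(config$n_score_arms), function(i)
      gen_score_arm(sprintf("FRS%02d", i), config)))
  als_corpus(arms)
}

#' Generate a synthetic single-arm trial
#'
#' One arm whose structural model is scaled by a treatment effect: the
#' hazard is multiplied by `effect` for OS (values below 1 prolong
#' survival), or the maximal decline is multiplied by `effect` for the
#' score endpoint (values below 1 slow decline). `effect = 1`
#' reproduces a placebo-like arm; fixtures for external-control tests.
#'
#' @param config A [generator_config()].
#' @param effect Positive multiplier on the hazard (OS) or on Emax
#'   (score).
#' @param endpoint `"OS"` or `"ALSFRS"`.
#' @param seed Optional seed.
#' @return A [study_arm()].
#' @export
generate_single_arm_trial <- function(config = generator_config(),
                                      effect = 1,
                                      endpoint = c("OS", "ALSFRS"),
                                      seed = NULL) {
  endpoint <- match.arg(endpoint)
  stopifnot(effect > 0)
  if (!is.null(seed)) set.seed(seed)
  if (endpoint == "OS") gen_os_arm("TRIAL", config, effect = effect)
  else gen_score_arm("TRIAL", config, effect = effect)
}
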