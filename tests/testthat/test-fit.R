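test_that("a synthetic ALSFRS corpus is recovered at realistic noise", {
  corpus <- generate_corpus(generator_config(seed = 203))
  f <- quiet_fit(corpus, "ALSFRS", n_starts = 2, seed = 1)
  expect_true(f$converged)
  est <- coef(f)
  expect_equal(unname(est["emax"]), 26.2, tolerance = 0.25)
  expect_equal(unname(est["et50"]), 17.5, tolerance = 0.25)
  expect_true(all(is.finite(f$estimates$se[1:3])))
  expect_s3_class(f$params, "emax_params")
  # the fit prints and summarizes without error
  expect_output(print(f), "ALSFRS")
  expect_output(print(summary(f)), "rse_pct")
})

test_that("a synthetic OS corpus recovers signs and location", {
  corpus <- generate_corpus(generator_config(seed = 301,
                                             monotonize = FALSE))
  f <- quiet_fit(corpus, "OS", n_starts = 2, seed = 1)
  expect_true(f$converged)
  est <- coef(f)
  expect_equal(unname(est["mu"]), 3.04, tolerance = 0.1)
  expect_gt(unname(est["theta_duration_months"]), 0)
  expect_lt(unname(est["theta_riluzole_frac"]), 0.1)
  # proportional-hazards predictions at the estimates track the data scale
  expect_equal(f$n_arms, 30L)
})

test_that("base-hazard selection prefers the generating family", {
  # data simulated from the lognormal family
  wins <- 0L
  for (s in 1:3) {
    corpus <- generate_corpus(small_config(n_os_arms = 10L,
                                           n_score_arms = 0L,
                                           seed = 400 + s))
    sel <- suppressMessages(select_base_hazard(
      corpus, candidates = c("lognormal", "weibull", "exponential"),
      n_starts = 1))
    if (sel$table$hazard[1] == "lognormal") wins <- wins + 1L
    expect_true(all(diff(sel$table$aic) >= 0))
  }
  expect_gte(wins, 2L)
  # a single requested candidate yields a one-row table
  corpus <- generate_corpus(small_config(n_os_arms = 8L, n_score_arms = 0L,
                                         seed = 410))
  sel1 <- suppressMessages(select_base_hazard(corpus,
                                              candidates = "lognormal",
                                              n_starts = 1))
  expect_equal(nrow(sel1$table), 1L)
})

test_that("exponential data rank the exponential family near the top", {
  cfg <- small_config(
    n_os_arms = 10L, n_score_arms = 0L,
    os_params = alsmbma:::os_params_general(
      "exponential", base = c(rate = log(2) / 20),
      eta_sd = c(rate = 0.1), eps_sd = 0.4, obs_scale = "logit"),
    seed = 420)
  corpus <- generate_corpus(cfg)
  sel <- suppressMessages(select_base_hazard(
    corpus, candidates = c("lognormal", "weibull", "exponential"),
    n_starts = 1))
  expect_lte(match("exponential", sel$table$hazard), 2L)
})

test_that("covariate search keeps true effects and drops null ones", {
  # the true duration effect must always be retained; the null covariate
  # may enter by chance at the test's error rate, so it is checked
  # across seeds
  dur_kept <- 0L; male_dropped <- 0L
  strong <- os_params(mu = 3.04, sigm = 0.916,
                      theta_duration = 0.08, theta_riluzole = -0.228,
                      eta_sd_mu = 0.072, eta_sd_sigm = 0.252,
                      eps_sd = 0.693)
  for (s in 1:3) {
    corpus <- generate_corpus(generator_config(n_os_arms = 16L,
                                               n_score_arms = 0L,
                                               os_params = strong,
                                               seed = 429 + s,
                                               monotonize = FALSE))
    cs <- suppressMessages(suppressWarnings(covariate_search(
      corpus, "OS",
      candidates = list(list(cov = "duration_months", on = "hazard"),
                        list(cov = "male_frac", on = "hazard")),
      n_starts = 1)))
    inc <- vapply(cs$included, `[[`, character(1), "cov")
    if ("duration_months" %in% inc) dur_kept <- dur_kept + 1L
    if (!("male_frac" %in% inc)) male_dropped <- male_dropped + 1L
    expect_true(all(c("step", "covariate", "ofv", "delta_ofv", "decision")
                    %in% names(cs$trace)))
  }
  expect_equal(dur_kept, 3L)
  expect_gte(male_dropped, 2L)
})

test_that("ALSFRS covariate search returns the base model under the null", {
  corpus <- generate_corpus(generator_config(n_os_arms = 0L,
                                             n_score_arms = 14L,
                                             seed = 440))
  cs <- suppressMessages(covariate_search(
    corpus, "ALSFRS",
    candidates = list(list(cov = "riluzole_frac", on = "emax")),
    n_starts = 1))
  expect_length(cs$included, 0L)
  base <- quiet_fit(corpus, "ALSFRS", n_starts = 1)
  expect_equal(cs$fit$ofv, base$ofv, tolerance = 1e-4)
})

test_that("an empty candidate list reduces to the plain fit", {
  corpus <- generate_corpus(generator_config(n_os_arms = 0L,
                                             n_score_arms = 10L,
                                             seed = 450))
  cs <- suppressMessages(covariate_search(corpus, "ALSFRS",
                                          candidates = list(),
                                          n_starts = 1))
  f <- quiet_fit(corpus, "ALSFRS", n_starts = 1)
  expect_equal(cs$fit$ofv, f$ofv, tolerance = 1e-6)
})

test_that("empirical-Bayes modes vanish for on-curve studies and shrink", {
  corpus <- generate_corpus(generator_config(n_os_arms = 0L,
                                             n_score_arms = 12L,
                                             seed = 460))
  f <- quiet_fit(corpus, "ALSFRS", n_starts = 2, seed = 1)
  p <- f$params
  # a pseudo-corpus whose arms sit exactly on the fitted typical curve
  tt <- c(6, 12, 24, 36)
  on_curve <- als_corpus(lapply(1:3, function(i)
    study_arm(sprintf("C%d", i), 75, covariate_profile(17.8, 0.9),
              score_series = data.frame(time_months = tt,
                                        mean_change =
                                          typical_change(tt, p)))))
  eb0 <- empirical_bayes(f, on_curve)
  expect_lt(max(abs(eb0$eta_emax)), 1e-4)
  expect_lt(max(abs(eb0$eta_gamma)), 1e-4)
  # shrinkage: the EB mode is pulled toward zero relative to the
  # unpenalized per-study MLE, and trades data fit for the prior
  eb <- empirical_bayes(f)
  prep <- f$prep
  for (i in seq_len(min(5, prep$n_arms))) {
    sel <- prep$arm == i
    ssr <- function(eta) {
      pr <- typical_change(prep$t[sel], p, eta)
      sum((prep$y[sel] - pr)^2)
    }
    eta_eb <- c(eb$eta_emax[i], eb$eta_gamma[i])
    mle <- stats::optim(eta_eb, ssr, method = "BFGS")$par
    expect_lte(sqrt(sum(eta_eb^2)), sqrt(sum(mle^2)) + 1e-6)
    expect_gte(ssr(eta_eb), ssr(mle) - 1e-8)
  }
})

test_that("conditional precision grows with the number of observations", {
  corpus <- generate_corpus(generator_config(n_os_arms = 0L,
                                             n_score_arms = 12L,
                                             seed = 470))
  f <- quiet_fit(corpus, "ALSFRS", n_starts = 1)
  p <- f$params
  mk_arm <- function(id, k) {
    tt <- seq(6, 6 * k, by = 6)
    study_arm(id, 75, covariate_profile(17.8, 0.9),
              score_series = data.frame(
                time_months = tt,
                mean_change = typical_change(tt, p, c(0.1, 0))))
  }
  two <- als_corpus(list(mk_arm("short", 2L), mk_arm("long", 8L),
                         mk_arm("pad", 4L)))
  eb <- empirical_bayes(f, two)
  expect_lt(eb$cond_sd_emax[eb$study_id == "long"],
            eb$cond_sd_emax[eb$study_id == "short"])
})

test_that("reported-SE residual weighting is honored when requested", {
  set.seed(480)
  mk <- function(id, se_val) {
    tt <- seq(6, 36, by = 6)
    ch <- typical_change(tt, ref_emax) + rnorm(length(tt), 0, se_val)
    study_arm(id, 75, covariate_profile(17.8, 0.9),
              score_series = data.frame(time_months = tt,
                                        mean_change = pmax(ch, -48),
                                        se = se_val))
  }
  corpus <- als_corpus(c(lapply(1:4, function(i) mk(sprintf("A%d", i), 1)),
                         lapply(1:4, function(i) mk(sprintf("B%d", i), 3))))
  f <- quiet_fit(corpus, "ALSFRS", n_starts = 1, weighting = "se")
  expect_true(f$converged)
  # eps_sd is calibrated to the median reported SE (here between 1 and 3)
  expect_gt(unname(coef(f)["eps_sd"]), 0.5)
  expect_lt(unname(coef(f)["eps_sd"]), 6)
  # missing SEs are refused
  no_se <- als_corpus(lapply(1:4, function(i) {
    a <- mk(sprintf("C%d", i), 1)
    a$score_series$se <- NA_real_
    a
  }))
  expect_error(quiet_fit(no_se, "ALSFRS", weighting = "se"), "SE")
  expect_error(quiet_fit(generate_corpus(small_config(seed = 481)), "OS",
                         weighting = "se"), "score endpoint")
})
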