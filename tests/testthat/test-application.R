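test_that("printed confidence intervals convert to standard errors", {
  expect_equal(ci_to_se(-9.57, -6.72), 2.85 / 3.92, tolerance = 1e-3)
  expect_equal(ci_to_se(-12.75, -7.45), 5.30 / 3.92, tolerance = 1e-3)
  expect_equal(ci_to_se(-1.959964, 1.959964), 1.0, tolerance = 1e-6)
  expect_error(ci_to_se(2, 1), "exceed")
})

test_that("the conjugate update reproduces the published posterior", {
  prior <- arm_summary(-8.07, -9.57, -6.72)
  obs <- arm_summary(-10.1, -12.75, -7.45)
  post <- conjugate_update(prior, obs)
  expect_equal(post$mean, -8.53, tolerance = 0.02)
  expect_equal(post$lo95, -9.79, tolerance = 0.02)
  expect_equal(post$hi95, -7.27, tolerance = 0.02)
  expect_true(post$borrow_weight > 0.5)  # the prior is the sharper source
  # posterior mean lies strictly between prior and observed means
  expect_true(post$mean > obs$mean && post$mean < prior$mean)
  expect_lt(post$sd, min(prior$se, obs$se))
})

test_that("conjugate limits: flat prior and equal-precision identity", {
  obs <- arm_summary(-10.1, -12.75, -7.45)
  flat <- arm_summary(0, -1e6, 1e6)
  post <- conjugate_update(flat, obs)
  expect_equal(post$mean, obs$mean, tolerance = 1e-4)
  expect_equal(post$sd, obs$se, tolerance = 1e-4)
  same <- conjugate_update(obs, obs)
  expect_equal(same$mean, obs$mean)
  expect_equal(same$sd, obs$se / sqrt(2), tolerance = 1e-12)
})

test_that("a Metropolis sampler reproduces the conjugate posterior", {
  prior <- arm_summary(-8.07, -9.57, -6.72)
  obs <- arm_summary(-10.1, -12.75, -7.45)
  post <- conjugate_update(prior, obs)
  draws <- alsmbma:::metropolis_posterior(prior, obs, n_draws = 50000L,
                                          seed = 31)
  draws <- draws[-(1:2000)]
  expect_equal(mean(draws), post$mean, tolerance = abs(post$mean) * 0.01)
  expect_equal(stats::sd(draws), post$sd, tolerance = post$sd * 0.05)
})

test_that("relative-efficacy reports match the published figures", {
  prior <- arm_summary(-8.07, -9.57, -6.72)
  obs <- arm_summary(-10.1, -12.75, -7.45)
  post <- conjugate_update(prior, obs)
  drug <- arm_summary(-7.1, -9.04, -5.16)
  rep1 <- borrow_report(post, drug)
  expect_equal(rep1$relative_pct, 17, tolerance = 1)
  # no borrowing: trial placebo against the drug arm
  rep2 <- borrow_report(obs, drug)
  expect_equal(rep2$relative_pct, 30, tolerance = 1)
  # identical arms: zero relative difference
  rep3 <- borrow_report(post, arm_summary(post$mean, post$lo95, post$hi95))
  expect_equal(rep3$relative_pct, 0)
})

test_that("external-control verdicts classify constructed series", {
  cv <- covariate_profile(19.2, 0.72)
  tt <- c(4, 8, 12, 16)
  typical <- os_survival(tt, cv, ref_os)
  # on the typical curve: inside, no difference
  r0 <- external_control_compare(ref_os, cv,
                                 data.frame(time_months = tt,
                                            value = typical),
                                 endpoint = "OS", n = 87,
                                 n_mc = 400, seed = 1)
  expect_equal(r0$verdict, "no difference")
  expect_true(all(r0$table$class == "inside"))
  # uniformly below the band: the failed-trial pattern
  below <- pmax(r0$table$lo95 * 0.5, 1e-4)
  r1 <- external_control_compare(ref_os, cv,
                                 data.frame(time_months = tt,
                                            value = below),
                                 endpoint = "OS", n = 87,
                                 n_mc = 400, seed = 1)
  expect_equal(r1$verdict, "inferior/no benefit")
  # a score series above the upper typical-value band: superior
  tt2 <- c(3, 6, 9)
  r2 <- external_control_compare(ref_emax, covariate_profile(17.8, 0.9),
                                 data.frame(time_months = tt2,
                                            value = c(-0.1, -0.2, -0.3)),
                                 endpoint = "ALSFRS", n = NULL,
                                 include_eta = FALSE,
                                 n_mc = 400, seed = 1)
  expect_equal(r2$verdict, "superior")
  expect_true(all(r2$table$class == "above"))
})

test_that("a placebo-like synthetic trial falls inside the placebo band", {
  inside_frac <- vapply(1:5, function(s) {
    cfg <- generator_config(seed = NULL)
    arm <- generate_single_arm_trial(cfg, effect = 1, endpoint = "ALSFRS",
                                     seed = 900 + s)
    r <- external_control_compare(
      ref_emax, arm$covariates,
      data.frame(time_months = arm$score_series$time_months,
                 value = arm$score_series$mean_change),
      endpoint = "ALSFRS", n = arm$n, n_mc = 300, seed = s)
    mean(r$table$class == "inside")
  }, numeric(1))
  expect_gte(mean(inside_frac), 0.9)
})

test_that("a strong hazard reduction escapes the band at late times", {
  frac_above <- vapply(1:6, function(s) {
    # a trial-sized arm (late observations carry the survival benefit)
    cfg <- generator_config(n_range = c(87L, 200L))
    arm <- generate_single_arm_trial(cfg, effect = 0.4, endpoint = "OS",
                                     seed = 950 + s)
    late <- arm$os_series$time_months >= 24
    r <- external_control_compare(
      ref_os, arm$covariates,
      data.frame(time_months = arm$os_series$time_months,
                 value = arm$os_series$surv_prob)[late, ],
      endpoint = "OS", n = NULL, include_eta = FALSE,
      n_mc = 300, seed = s)
    mean(r$table$class == "above")
  }, numeric(1))
  expect_gt(mean(frac_above), 0.5)
  expect_gte(sum(frac_above > 0.5), 3L)
})
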