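test_that("the generator is deterministic given a seed", {
  c1 <- generate_corpus(generator_config(seed = 5))
  c2 <- generate_corpus(generator_config(seed = 5))
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- generate_corpus(generator_config(seed = 6))
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
})

test_that("zero variability puts observations on the structural curves", {
  cfg <- generator_config(
    n_os_arms = 3L, n_score_arms = 3L,
    os_params = os_params(3.04, 0.916, 0.0317, -0.228),
    emax_params = emax_params(26.2, 17.5, 1.2), seed = 12)
  corpus <- generate_corpus(cfg)
  for (a in corpus$arms) {
    if (nrow(a$os_series)) {
      expect_equal(a$os_series$surv_prob,
                   os_survival(a$os_series$time_months, a$covariates,
                               cfg$os_params), tolerance = 1e-9)
    } else {
      expect_equal(a$score_series$mean_change,
                   typical_change(a$score_series$time_months,
                                  cfg$emax_params), tolerance = 1e-9)
    }
  }
})

test_that("corpus composition matches the configured study conditions", {
  meds_n <- numeric(4); meds_d <- numeric(4)
  for (s in 1:4) {
    corpus <- generate_corpus(generator_config(seed = 40 + s))
    os_arms <- Filter(function(a) nrow(a$os_series) > 0, corpus$arms)
    expect_length(os_arms, 30L)
    ns <- vapply(corpus$arms, `[[`, numeric(1), "n")
    expect_true(all(ns >= 11 & ns <= 468))
    meds_n[s] <- stats::median(ns)
    dur <- vapply(corpus$arms, function(a) a$covariates$duration_months,
                  numeric(1))
    expect_true(all(dur >= 9 & dur <= 36))
    meds_d[s] <- stats::median(dur)
    ril <- vapply(corpus$arms, function(a) a$covariates$riluzole_frac,
                  numeric(1))
    expect_true(all(ril >= 0 & ril <= 1))
  }
  expect_gte(mean(meds_n), 40); expect_lte(mean(meds_n), 120)
  expect_gte(mean(meds_d), 15); expect_lte(mean(meds_d), 25)
})

test_that("survival series are monotone after noise by default", {
  corpus <- generate_corpus(generator_config(seed = 77))
  for (a in corpus$arms)
    if (nrow(a$os_series))
      expect_true(all(diff(a$os_series$surv_prob) <= 1e-12))
})

test_that("single-arm trials scale the structural model by the effect", {
  cfg <- generator_config(
    emax_params = emax_params(26.2, 17.5, 1.2),  # no noise
    os_params = os_params(3.04, 0.916, 0.0317, -0.228))
  arm <- generate_single_arm_trial(cfg, effect = 1, endpoint = "ALSFRS",
                                   seed = 3)
  expect_equal(arm$score_series$mean_change,
               typical_change(arm$score_series$time_months,
                              cfg$emax_params), tolerance = 1e-9)
  half <- generate_single_arm_trial(cfg, effect = 0.5, endpoint = "ALSFRS",
                                    seed = 3)
  expect_equal(half$score_series$mean_change,
               0.5 * typical_change(half$score_series$time_months,
                                    cfg$emax_params), tolerance = 1e-9)
  os1 <- generate_single_arm_trial(cfg, effect = 0.4, endpoint = "OS",
                                   seed = 3)
  expect_equal(os1$os_series$surv_prob,
               os_survival(os1$os_series$time_months, os1$covariates,
                           cfg$os_params)^0.4, tolerance = 1e-9)
  expect_error(generate_single_arm_trial(cfg, effect = -1), "effect")
})

test_that("YAML configuration overrides generator fields", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_os_arms: 4", "n_score_arms: 2", "seed: 9",
               "emax_params:", "  emax: 20", "  et50: 12",
               "  gamma: 1.5"), path)
  cfg <- read_generator_config(path)
  expect_equal(cfg$n_os_arms, 4L)
  expect_equal(cfg$emax_params$emax, 20)
  corpus <- generate_corpus(cfg)
  expect_equal(length(corpus), 6L)
})
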