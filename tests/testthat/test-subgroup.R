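test_that("DerSimonian-Laird pooling matches hand-computed values", {
  # three studies, unit SEs: Q = 2, tau2 = max(0, (2-2)/(3-1)) = 0
  p <- pool_random_effects(c(1, 2, 3), c(1, 1, 1))
  expect_equal(p$mean, 2)
  expect_equal(p$tau2, 0)
  expect_equal(p$se, 1 / sqrt(3))
  expect_equal(p$Q, 2)
  # single study passes through
  p1 <- pool_random_effects(1.0, 0.2)
  expect_equal(p1$mean, 1.0)
  expect_equal(p1$se, 0.2)
  expect_equal(p1$tau2, 0)
  # equal values: no heterogeneity, pooled mean is the common value
  pe <- pool_random_effects(c(2.5, 2.5, 2.5), c(0.3, 0.5, 0.7))
  expect_equal(pe$mean, 2.5)
  expect_equal(pe$tau2, 0)
  expect_error(pool_random_effects(numeric(0), numeric(0)), "at least one")
})

test_that("pooling agrees with the metafor reference implementation", {
  skip_if_not_installed("metafor")
  set.seed(42)
  yi <- rnorm(8, 1.5, 0.8)
  sei <- runif(8, 0.2, 0.9)
  ours <- pool_random_effects(yi, sei)
  ref <- metafor::rma.uni(yi = yi, sei = sei, method = "DL")
  expect_equal(ours$mean, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(ours$se, ref$se, tolerance = 1e-10)
  expect_equal(ours$tau2, ref$tau2, tolerance = 1e-10)
})

test_that("heterogeneous studies and the fixed-effect degenerate case", {
  yi <- c(0, 4)
  sei <- c(1, 1)
  p <- pool_random_effects(yi, sei)
  # Q = 8, tau2 = (8 - 1)/(2 - 0.5... ) hand computation:
  # sum w = 2, sum w^2 = 2, denom = 2 - 1 = 1, tau2 = (8-1)/1 = 7
  expect_equal(p$tau2, 7)
  wstar <- 1 / (1 + 7)
  expect_equal(p$se, 1 / sqrt(2 * wstar))
  # when tau2 = 0, pooling equals inverse-variance fixed effect
  yi2 <- c(1.0, 1.1, 0.9)
  sei2 <- c(1, 2, 2)
  p2 <- pool_random_effects(yi2, sei2)
  expect_equal(p2$tau2, 0)
  w <- 1 / sei2^2
  expect_equal(p2$mean, sum(w * yi2) / sum(w))
  expect_equal(p2$se, 1 / sqrt(sum(w)))
})

test_that("a whole-corpus subgroup tracks the typical simulation", {
  corpus <- generate_corpus(generator_config(n_os_arms = 0L,
                                             n_score_arms = 14L,
                                             seed = 710))
  f <- quiet_fit(corpus, "ALSFRS", n_starts = 1)
  # degenerate split: every arm on one side (cutpoint below the range)
  sg <- suppressWarnings(subgroup_analysis(
    f, list(subgroup_spec("duration_months", cutpoint = 0)),
    n_mc = 400, seed = 1, landmark = 12))
  expect_equal(nrow(sg), 1L)
  expect_equal(sg$k, f$n_arms)
  expect_equal(sg$estimate, typical_change(12, f$params), tolerance = 0.8)
})

test_that("a shifted subgroup is detected and a null one is not", {
  base_em <- emax_params(26.2, 17.5, 1.2, eta_sd_emax = 0.10,
                         eta_sd_gamma = 0.05, eps_sd = 2)
  detected <- 0L; null_sep <- 0L
  for (s in 1:3) {
    set.seed(800 + s)
    mk <- function(id, emax_i) {
      tt <- seq(6, 36, by = 6)
      ch <- typical_change(tt, emax_params(emax_i, 17.5, 1.2)) +
        rnorm(length(tt), 0, 1.0)
      study_arm(id, 75,
                covariate_profile(17.8, 0.9,
                                  male_frac = runif(1, 0.45, 0.72),
                                  pub_year = sample(1995:2020, 1)),
                score_series = data.frame(time_months = tt,
                                          mean_change = pmax(ch, -48)))
    }
    # pub_year split is null; high-emax arms get a +35% shifted Emax
    arms <- c(lapply(1:6, function(i) mk(sprintf("lo%d", i), 22)),
              lapply(1:6, function(i) mk(sprintf("hi%d", i), 30)))
    for (i in 1:6) arms[[i]]$covariates$male_frac <- runif(1, 0.45, 0.55)
    for (i in 7:12) arms[[i]]$covariates$male_frac <- runif(1, 0.62, 0.72)
    corpus <- als_corpus(arms)
    f <- quiet_fit(corpus, "ALSFRS", n_starts = 1)
    sg <- suppressWarnings(subgroup_analysis(
      f, list(subgroup_spec("male_frac"), subgroup_spec("pub_year")),
      n_mc = 300, seed = s, landmark = 12))
    male <- sg[sg$variable == "male_frac", ]
    hi <- male[grepl("^>", male$level), ]
    lo <- male[grepl("^<=", male$level), ]
    if (nrow(hi) == 1 && nrow(lo) == 1 && hi$estimate < lo$estimate)
      detected <- detected + 1L
    yr <- sg[sg$variable == "pub_year", ]
    if (nrow(yr) == 2) {
      gap <- abs(yr$estimate[1] - yr$estimate[2])
      halfw <- max((yr$hi95 - yr$lo95) / 2)
      if (gap < halfw) null_sep <- null_sep + 1L
    }
  }
  expect_gte(detected, 2L)
  expect_gte(null_sep, 2L)
})
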