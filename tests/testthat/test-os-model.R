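test_that("log hazard multiplier combines centered covariates", {
  expect_equal(log_hazard_multiplier(covariate_profile(17.8, 0), ref_os), 0)
  # 10 months above the centering point at the published coefficient
  expect_equal(log_hazard_multiplier(covariate_profile(27.8, 0), ref_os),
               10 * 0.0317, tolerance = 1e-12)
  expect_equal(log_hazard_multiplier(covariate_profile(17.8, 1), ref_os),
               -0.228, tolerance = 1e-12)
  cv_missing <- covariate_profile(17.8, 0.9)
  cv_missing$duration_months <- NA_real_
  expect_error(log_hazard_multiplier(cv_missing, ref_os), "missing")
})

test_that("survival matches the cumulative-hazard quadrature oracle", {
  cv <- covariate_profile(24, 0.7)
  hr <- exp(log_hazard_multiplier(cv, ref_os))
  for (t in c(6, 12, 24, 60)) {
    chaz <- stats::integrate(function(u) {
      h0 <- stats::dlnorm(u, ref_os$mu, ref_os$sigm) /
        (1 - stats::plnorm(u, ref_os$mu, ref_os$sigm))
      h0 * hr
    }, 0, t, rel.tol = 1e-10)$value
    expect_equal(os_survival(t, cv, ref_os), exp(-chaz), tolerance = 1e-6)
  }
  expect_equal(os_survival(0, cv, ref_os), 1)
  expect_error(os_survival(-1, cv, ref_os), "nonnegative")
})

test_that("lognormal median identity holds with unit hazard ratio", {
  cv0 <- covariate_profile(17.8, 0)
  expect_equal(os_survival(exp(ref_os$mu), cv0, ref_os), 0.5,
               tolerance = 1e-12)
  expect_equal(median_os(cv0, ref_os), exp(3.04), tolerance = 1e-5)
})

test_that("median solver agrees with a dense-grid scan", {
  cv <- covariate_profile(17.8, 1)
  med <- median_os(cv, ref_os)
  grid <- seq(1e-3, 100, by = 1e-3)
  scan <- grid[which.min(abs(os_survival(grid, cv, ref_os) - 0.5))]
  expect_equal(med, scan, tolerance = 1e-3)
  expect_equal(med, 25.23, tolerance = 0.01)
  # unreachable median within the horizon errors
  slow <- os_params(mu = 7, sigm = 0.9)
  expect_error(median_os(covariate_profile(17.8, 0), slow), "horizon")
})

test_that("median OS is monotone in duration and riluzole", {
  meds_dur <- vapply(c(9, 18, 27, 36), function(d)
    median_os(covariate_profile(d, 0.9), ref_os), numeric(1))
  expect_true(all(diff(meds_dur) < 0))
  meds_ril <- vapply(c(0, 0.5, 1), function(r)
    median_os(covariate_profile(17.8, r), ref_os), numeric(1))
  expect_true(all(diff(meds_ril) > 0))
})

test_that("log(-log S) differences are constant in t (proportional hazards)", {
  cv1 <- covariate_profile(12, 0.2)
  cv2 <- covariate_profile(30, 0.95)
  tt <- c(3, 7.5, 12, 24, 48, 90)
  d <- log(-log(os_survival(tt, cv1, ref_os))) -
    log(-log(os_survival(tt, cv2, ref_os)))
  expect_lt(max(d) - min(d), 1e-8)
  expect_equal(d[1], log_hazard_multiplier(cv1, ref_os) -
                 log_hazard_multiplier(cv2, ref_os), tolerance = 1e-8)
})

test_that("survival is a proper non-increasing curve in (0, 1]", {
  cv <- covariate_profile(20, 0.5)
  tt <- seq(0, 120, by = 0.5)
  s <- os_survival(tt, cv, ref_os)
  expect_true(all(s > 0 & s <= 1))
  expect_true(all(diff(s) < 0))
})

test_that("predicted series respect the observation scale", {
  cv <- covariate_profile(17.8, 0)
  med <- median_os(cv, ref_os)
  arm <- study_arm("A", 75, cv,
                   os_series = data.frame(time_months = med,
                                          surv_prob = 0.5))
  expect_equal(predict_surv_series(arm, ref_os, scale = "identity"), 0.5,
               tolerance = 1e-9)
  expect_equal(predict_surv_series(arm, ref_os, scale = "logit"), 0,
               tolerance = 1e-8)
  # cloglog equals ln(-ln S) recomputed directly
  set.seed(5)
  tt <- sort(stats::runif(5, 2, 50))
  arm2 <- study_arm("B", 75, cv,
                    os_series = data.frame(
                      time_months = tt,
                      surv_prob = os_survival(tt, cv, ref_os)))
  expect_equal(predict_surv_series(arm2, ref_os, scale = "cloglog"),
               log(-log(os_survival(tt, cv, ref_os))), tolerance = 1e-10)
  # boundary survival is clipped with a warning on transformed scales
  arm3 <- study_arm("C", 75, cv,
                    os_series = data.frame(time_months = 1e-8,
                                           surv_prob = 1))
  expect_warning(predict_surv_series(arm3, ref_os, scale = "logit"),
                 "clipped")
})

test_that("study random effects scale the base parameters multiplicatively", {
  cv <- covariate_profile(17.8, 0)
  eta <- c(0.1, -0.2)
  shifted <- os_params(mu = ref_os$mu * exp(0.1),
                       sigm = ref_os$sigm * exp(-0.2))
  expect_equal(os_survival(c(6, 12, 24), cv, ref_os, eta = eta),
               os_survival(c(6, 12, 24), cv, shifted), tolerance = 1e-12)
})
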