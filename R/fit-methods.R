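#' @export
print.mbma_fit <- function(x, ...) {
  cat(sprintf("Aggregate placebo-course model: endpoint %s%s\n", x$endpoint,
              if (x$endpoint == "OS")
                sprintf(" (%s base hazard, %s scale)", x$hazard, x$obs_scale)
              else ""))
  cat(sprintf("  %d arms, %d observations; OFV = %.3f; converged: %s\n",
              x$n_arms, x$n_obs, x$ofv, x$converged))
  est <- x$estimates
  cat("  estimates:", paste(sprintf("%s = %.4g", est$parameter,
                                    est$estimate), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mbma_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mbma_fit")
}

#' @export
print.summary.mbma_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nParameter estimates (observed-information SEs):\n")
  est <- f$estimates
  est$estimate <- signif(est$estimate, 4)
  est$se <- signif(est$se, 3)
  est$rse_pct <- round(est$rse_pct, 1)
  print(est, row.names = FALSE)
  cat(sprintf("\n-2 log marginal likelihood: %.3f (AIC %.3f)\n",
              f$ofv, f$ofv + 2 * f$n_par))
  invisible(x)
}

#' @export
coef.mbma_fit <- function(object, ...) {
  stats::setNames(object$estimates$estimate, object$estimates$parameter)
}

#' @export
logLik.mbma_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_par, nobs = object$n_obs,
            class = "logLik")
}

#' @export
vcov.mbma_fit <- function(object, scale = c("estimation", "natural"), ...) {
  scale <- match.arg(scale)
  v <- object$vcov_phi
  dimnames(v) <- list(names(object$phi), names(object$phi))
  if (scale == "estimation") return(v)
  prep <- object$prep
  d <- rep(1, prep$n_par)
  logidx <- c(prep$ib, prep$ie, prep$is_)
  d[logidx] <- exp(object$phi[logidx])
  v * outer(d, d)
}

#' Empirical-Bayes study-level effects
#'
#' @param object An `mbma_fit`.
#' @param ... Unused.
#' @return Data frame of per-study random-effect modes (`eta_*`) with
#'   conditional SDs.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @rdname ranef
#' @export
ranef.mbma_fit <- function(object, ...) {
  eb <- object$eb
  eb[, c("study_id", grep("^(eta_|cond_sd_)", names(eb), value = TRUE))]
}

#' Per-study parameter estimates from Bayesian post-hoc estimation
#'
#' Returns the study-level parameters `base * exp(eta_hat)` where
#' `eta_hat` are the posterior modes of the study random effects given
#' the population fit, with conditional SEs (delta method on the
#' conditional SD of eta). Covariate contributions are not part of these
#' parameters: they refer to the reference (centered-covariate) profile.
#' Studies whose data carry no information on a random effect return the
#' prior mode 0 with the prior SD.
#'
#' @param fit A converged `mbma_fit`.
#' @param corpus Optional corpus; defaults to the one stored in the fit.
#' @return Data frame with one row per contributing arm.
#' @export
empirical_bayes <- function(fit, corpus = NULL) {
  stopifnot(inherits(fit, "mbma_fit"))
  if (is.null(corpus)) return(fit$eb)
  prep <- prep_likelihood(corpus, fit$endpoint,
                          if (fit$endpoint == "OS") fit$hazard else "lognormal",
                          fit$covariates, fit$obs_scale, fit$weighting)
  sp <- split_phi(unname(fit$phi), prep)
  im <- inner_modes(prep, sp$base, sp$thetas, sp$om, sp$eps)
  hs <- if (sum(im$act) > 0L)
    arm_hessians(prep, sp$base, sp$thetas, sp$om, sp$eps, im$eta, im$act)
  else NULL
  build_eb_table(prep, sp, im, hs)
}

#' Model predictions for new covariate profiles or arms
#'
#' @param object An `mbma_fit`.
#' @param newdata A [covariate_profile()] (with `times` given) or a
#'   [study_arm()] (its own observation times are used).
#' @param times Prediction times in months (required with a covariate
#'   profile).
#' @param type `"response"` for the natural scale (survival proportion /
#'   score change) or `"link"` for the observation scale.
#' @param eta Study random effects (default zero: population prediction).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mbma_fit <- function(object, newdata = NULL, times = NULL,
                             type = c("response", "link"), eta = NULL, ...) {
  type <- match.arg(type)
  p <- object$params
  if (inherits(newdata, "study_arm")) {
    cov <- newdata$covariates
    if (is.null(times))
      times <- if (object$endpoint == "OS") newdata$os_series$time_months
      else newdata$score_series$time_months
  } else if (inherits(newdata, "covariate_profile")) {
    cov <- newdata
  } else if (is.null(newdata) && !is.null(times)) {
    cov <- NULL
  } else stop("newdata must be a study_arm or covariate_profile")
  if (is.null(times)) stop("prediction times are required")
  if (object$endpoint == "OS") {
    if (is.null(cov)) stop("OS predictions need a covariate profile")
    s <- os_survival(times, cov, p, eta)
    if (type == "response") s else link_surv(clip_surv(s), object$obs_scale)
  } else {
    if (is.null(eta)) eta <- c(0, 0)
    typical_change(times, p, eta)
  }
}

#' Simulate replicate corpora from a fitted model
#'
#' Draws study random effects and residual noise under the original
#' design (same arms, times, sizes, covariates) and returns replicate
#' corpora, the engine behind the visual predictive check.
#'
#' @param object An `mbma_fit`.
#' @param nsim Number of replicate corpora.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `als_corpus` objects of length `nsim`.
#' @export
simulate.mbma_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sims <- simulate_observations(object, n_sim = nsim, seed = seed)
  prep <- object$prep
  lapply(seq_len(nsim), function(s) {
    arms <- lapply(seq_len(prep$n_arms), function(i) {
      a <- prep$arms[[i]]
      sel <- prep$arm == i
      v <- sims[sel, s]
      if (object$endpoint == "OS") {
        v <- cummin(clip_surv(v, 1e-6, 1 - 1e-6))
        study_arm(a$study_id, a$n, a$covariates,
                  os_series = data.frame(time_months = prep$t[sel],
                                         surv_prob = v))
      } else {
        v <- pmax(pmin(v, 48), -48)
        study_arm(a$study_id, a$n, a$covariates,
                  score_series = data.frame(time_months = prep$t[sel],
                                            mean_change = v))
      }
    })
    als_corpus(arms)
  })
}

# Matrix of simulated observations (natural scale), n_obs x n_sim.
simulate_observations <- function(fit, n_sim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prep <- fit$prep
  sp <- split_phi(unname(fit$phi), prep)
  out <- matrix(NA_real_, prep$n_obs, n_sim)
  for (s in seq_len(n_sim)) {
    eta <- matrix(stats::rnorm(prep$n_arms * prep$q, 0,
                               rep(sp$om, each = prep$n_arms)),
                  prep$n_arms, prep$q)
    f <- struct_pred(prep, sp$base, sp$thetas, eta)
    y <- f + stats::rnorm(prep$n_obs, 0, prep$w * sp$eps)
    out[, s] <- if (fit$endpoint == "OS") {
      if (prep$obs_scale == "identity") pmin(pmax(y, 0), 1)
      else unlink_surv(y, prep$obs_scale)
    } else y
  }
  out
}

#' Residuals of an aggregate-model fit
#'
#' @param object An `mbma_fit`.
#' @param type `"cwres"` (conditional weighted residuals under the
#'   first-order covariance linearization) or `"pearson"`
#'   (individual-prediction residuals over the residual SD).
#' @param ... Unused.
#' @return Numeric vector, one value per observation.
#' @export
residuals.mbma_fit <- function(object, type = c("cwres", "pearson"), ...) {
  type <- match.arg(type)
  g <- gof(object)
  if (type == "cwres") g$cwres
  else (g$obs - g$ipred) / (object$prep$w * object$params$eps_sd)
}

#' Diagnostic plots for a fitted model
#'
#' Observation vs population/individual predictions and CWRES panels.
#'
#' @param x An `mbma_fit`.
#' @param which Subset of panels (1: obs vs PRED, 2: obs vs IPRED,
#'   3: CWRES vs PRED, 4: CWRES vs time).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mbma_fit <- function(x, which = 1:4, ...) {
  g <- gof(x)
  op <- graphics::par(mfrow = c(ceiling(length(which) / 2),
                                min(2, length(which))))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    graphics::plot(g$pred, g$obs, xlab = "PRED", ylab = "OBS", ...)
    graphics::abline(0, 1, lty = 2)
  }
  if (2 %in% which) {
    graphics::plot(g$ipred, g$obs, xlab = "IPRED", ylab = "OBS", ...)
    graphics::abline(0, 1, lty = 2)
  }
  if (3 %in% which) {
    graphics::plot(g$pred, g$cwres, xlab = "PRED", ylab = "CWRES", ...)
    graphics::abline(h = 0, lty = 2)
  }
  if (4 %in% which) {
    graphics::plot(g$time, g$cwres, xlab = "time (months)", ylab = "CWRES",
                   ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}
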