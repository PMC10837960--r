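#' Convert a printed confidence interval to a standard error
#'
#' `(hi - lo) / (2 z)` with `z` the standard-normal quantile at
#' `(1 + level)/2`; asymmetry of a printed interval is absorbed into
#' the full width.
#'
#' @param lo,hi Interval bounds (`hi > lo`).
#' @param level Confidence level (default 0.95).
#' @return The implied standard error.
#' @export
#' @examples
#' ci_to_se(-9.57, -6.72)  # about 0.727
ci_to_se <- function(lo, hi, level = 0.95) {
  if (hi <= lo) stop("hi must exceed lo")
  z <- stats::qnorm((1 + level) / 2)
  (hi - lo) / (2 * z)
}

#' Summary of a single trial arm endpoint
#'
#' @param mean Point estimate (e.g. mean ALSFRS-R change).
#' @param lo95,hi95 95% interval bounds.
#' @param n Optional sample size.
#' @param endpoint Endpoint label.
#' @return An object of class `arm_summary`.
#' @export
arm_summary <- function(mean, lo95, hi95, n = NA_integer_, endpoint = "") {
  if (!(lo95 <= mean && mean <= hi95))
    stop("need lo95 <= mean <= hi95")
  structure(list(mean = mean, lo95 = lo95, hi95 = hi95,
                 se = ci_to_se(lo95, hi95), n = n, endpoint = endpoint),
            class = "arm_summary")
}

#' @export
print.arm_summary <- function(x, ...) {
  cat(sprintf("%s: %.3g (95%% CI %.3g, %.3g), se %.3g\n",
              if (nzchar(x$endpoint)) x$endpoint else "arm",
              x$mean, x$lo95, x$hi95, x$se))
  invisible(x)
}

#' Conjugate normal-normal update of a small placebo arm
#'
#' Combines a historical prior with an observed arm by precision
#' weighting: `post_prec = 1/se_p^2 + 1/se_o^2`,
#' `post_mean = (mean_p/se_p^2 + mean_o/se_o^2) / post_prec`,
#' `post_sd = post_prec^(-1/2)`. The `borrow_weight` is the fraction of
#' the posterior precision contributed by the prior, which quantifies
#' how much the historical model effectively expands the placebo sample.
#'
#' @param prior,observed [arm_summary()] objects on the same endpoint
#'   and sign convention.
#' @return An object of class `posterior_summary`: `mean`, `sd`,
#'   `lo95`/`hi95` (`mean -/+ 1.96 sd`), `borrow_weight`, with the prior
#'   and likelihood echoed.
#' @export
#' @examples
#' prior <- arm_summary(-8.07, -9.57, -6.72)
#' obs <- arm_summary(-10.1, -12.75, -7.45)
#' conjugate_update(prior, obs)  # posterior about -8.53
conjugate_update <- function(prior, observed) {
  stopifnot(inherits(prior, "arm_summary"), inherits(observed, "arm_summary"))
  wp <- 1 / prior$se^2
  wo <- 1 / observed$se^2
  prec <- wp + wo
  m <- (prior$mean * wp + observed$mean * wo) / prec
  sd <- 1 / sqrt(prec)
  structure(list(mean = m, sd = sd,
                 lo95 = m - 1.96 * sd, hi95 = m + 1.96 * sd,
                 borrow_weight = wp / prec,
                 prior = prior, observed = observed),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("posterior: %.3f (95%% CI %.3f, %.3f), sd %.3f\n",
              x$mean, x$lo95, x$hi95, x$sd))
  cat(sprintf("prior contributes %.0f%% of the posterior precision\n",
              100 * x$borrow_weight))
  invisible(x)
}

#' Compare a single-arm trial with the simulated historical placebo band
#'
#' Simulates the matched placebo response at the trial's covariate
#' profile ([simulate_typical()]) and classifies each observed point
#' against the 95% band. By default the band is a prediction band for a
#' new arm of the trial's size: between-study effects and residual noise
#' (scaled by `sqrt(75/n)`) are included on top of parameter
#' uncertainty; set `include_eta = FALSE` and `n = NULL` for the
#' narrower typical-value band. The beneficial direction is
#' endpoint-specific: higher survival for OS, less negative change for
#' ALSFRS-R. The verdict is `"superior"` when most points lie outside
#' the band in the beneficial direction, `"inferior/no benefit"` when
#' most lie outside in the harmful direction, `"no difference"`
#' otherwise.
#'
#' @param x A converged OS/ALSFRS `mbma_fit` or a parameter object with
#'   RSEs.
#' @param trial_cov The trial's [covariate_profile()].
#' @param trial_series Data frame with `time_months` and `value`
#'   (survival proportion or mean ALSFRS-R change).
#' @param endpoint `"OS"` or `"ALSFRS"` (required for parameter
#'   objects; inferred from a fit).
#' @param n Trial arm size for residual scaling (`NULL` to omit
#'   residual noise from the band).
#' @param n_mc Monte-Carlo draws (default 1000).
#' @param seed Optional seed.
#' @param include_eta Include between-study variability (default TRUE).
#' @return An object of class `external_control`: per-time verdicts and
#'   the overall conclusion.
#' @export
external_control_compare <- function(x, trial_cov, trial_series,
                                     endpoint = NULL, n = NULL,
                                     n_mc = 1000L, seed = NULL,
                                     include_eta = TRUE) {
  if (inherits(x, "mbma_fit")) endpoint <- x$endpoint
  if (is.null(endpoint))
    endpoint <- if (inherits(x, "os_params")) "OS" else "ALSFRS"
  ts <- as.data.frame(trial_series)
  stopifnot(all(c("time_months", "value") %in% names(ts)))
  times <- sort(unique(c(0, ts$time_months)))
  spec <- uncertainty_spec(x)
  p_hat <- spec$params
  if (!is.null(seed)) set.seed(seed)
  sims <- matrix(NA_real_, nrow(ts), n_mc)
  w <- if (!is.null(n)) sqrt(MEDIAN_ARM_N / n) else 0
  for (m in seq_len(n_mc)) {
    phi_d <- spec$phi + stats::rnorm(length(spec$phi), 0, spec$se)
    p <- params_from_phi_draw(spec, phi_d)
    eta <- if (include_eta) stats::rnorm(length(p$eta_sd), 0, p$eta_sd)
    else NULL
    if (endpoint == "OS") {
      f <- link_surv(clip_surv(os_survival(ts$time_months, trial_cov, p,
                                           eta)), p$obs_scale)
      y <- f + stats::rnorm(nrow(ts), 0, w * p$eps_sd)
      sims[, m] <- unlink_surv(y, p$obs_scale)
    } else {
      eta2 <- if (is.null(eta)) c(0, 0) else eta
      f <- typical_change(ts$time_months, p, eta2)
      sims[, m] <- f + stats::rnorm(nrow(ts), 0, w * p$eps_sd)
    }
  }
  lo <- apply(sims, 1L, stats::quantile, 0.025, type = 7)
  hi <- apply(sims, 1L, stats::quantile, 0.975, type = 7)
  cls <- ifelse(ts$value > hi, "above", ifelse(ts$value < lo, "below",
                                               "inside"))
  beneficial <- "above"  # higher survival / less negative change
  harmful <- "below"
  fb <- mean(cls == beneficial)
  fh <- mean(cls == harmful)
  verdict <- if (fb > 0.5) "superior"
  else if (fh > 0.5) "inferior/no benefit"
  else "no difference"
  structure(list(table = data.frame(time_months = ts$time_months,
                                    observed = ts$value, lo95 = lo,
                                    hi95 = hi, class = cls,
                                    stringsAsFactors = FALSE),
                 verdict = verdict, endpoint = endpoint, n_mc = n_mc,
                 include_eta = include_eta, n = n),
            class = "external_control")
}

#' @export
print.external_control <- function(x, ...) {
  cat(sprintf("External-control comparison (%s): verdict %s\n",
              x$endpoint, x$verdict))
  print(transform(x$table, lo95 = signif(lo95, 4), hi95 = signif(hi95, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Relative-efficacy report after Bayesian borrowing
#'
#' Reports the drug effect relative to the (borrowing-sharpened)
#' placebo estimate: `100 * (|placebo| - |drug|) / |placebo|` percent
#' less decline, plus whether the 95% intervals overlap.
#'
#' @param post A `posterior_summary` (or `arm_summary` for a
#'   no-borrowing comparison).
#' @param drug An [arm_summary()] for the drug arm, same endpoint and
#'   sign convention.
#' @return A list of class `borrow_report`: `relative_pct`,
#'   `ci_overlap`, and the inputs.
#' @export
#' @examples
#' post <- conjugate_update(arm_summary(-8.07, -9.57, -6.72),
#'                          arm_summary(-10.1, -12.75, -7.45))
#' borrow_report(post, arm_summary(-7.1, -9.04, -5.16))  # ~17% less
borrow_report <- function(post, drug) {
  stopifnot(inherits(drug, "arm_summary"))
  if (abs(post$mean) < .Machine$double.eps)
    stop("posterior mean is zero; relative efficacy undefined")
  rel <- 100 * (abs(post$mean) - abs(drug$mean)) / abs(post$mean)
  overlap <- post$lo95 <= drug$hi95 && drug$lo95 <= post$hi95
  structure(list(relative_pct = rel, ci_overlap = overlap,
                 post = post, drug = drug),
            class = "borrow_report")
}

#' @export
print.borrow_report <- function(x, ...) {
  cat(sprintf("drug declines %.1f%% less than placebo (95%% CIs %s)\n",
              x$relative_pct,
              if (x$ci_overlap) "overlap" else "do not overlap"))
  invisible(x)
}

# Metropolis sampler for the same normal likelihood x normal prior;
# numerical cross-check of the conjugate posterior.
metropolis_posterior <- function(prior, observed, n_draws = 50000L,
                                 seed = NULL, proposal_sd = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(proposal_sd)) proposal_sd <- prior$se
  logpost <- function(th)
    stats::dnorm(observed$mean, th, observed$se, log = TRUE) +
    stats::dnorm(th, prior$mean, prior$se, log = TRUE)
  th <- prior$mean
  lp <- logpost(th)
  out <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    cand <- th + stats::rnorm(1, 0, proposal_sd)
    lp_c <- logpost(cand)
    if (log(stats::runif(1)) < lp_c - lp) {
      th <- cand; lp <- lp_c
    }
    out[i] <- th
  }
  out
}
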