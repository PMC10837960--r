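#' Parameters of the overall-survival model
#'
#' Log-normal base hazard with a proportional-hazards covariate model.
#' The base survival is `S0(t) = 1 - pnorm((log t - mu) / sigm)` and a
#' covariate profile multiplies the hazard by
#' `exp(theta_duration * (duration - duration_center) +
#' theta_riluzole * riluzole_frac)`, so `S(t) = S0(t)^HR`. Study-level
#' random effects act multiplicatively on the base parameters
#' (`mu * exp(eta_mu)`, `sigm * exp(eta_sigm)`); their SDs are stored as
#' coefficients of variation (fractions, e.g. 0.252 for 25.2%). The
#' residual SD `eps_sd` lives on the configured observation scale
#' (default `logit` of the survival proportion) and applies to an arm of
#' the corpus-median size (75); an arm of size n has residual SD
#' `eps_sd * sqrt(75 / n)`.
#'
#' @param mu Location of log survival time (log months).
#' @param sigm Positive scale of log survival time.
#' @param theta_duration Covariate coefficient of disease duration on the
#'   log hazard, per month.
#' @param theta_riluzole Covariate coefficient of the riluzole-treated
#'   fraction on the log hazard, per unit fraction.
#' @param duration_center Centering constant for duration, months.
#' @param eta_sd_mu,eta_sd_sigm Between-study CVs (fractions) of `mu` and
#'   `sigm`.
#' @param eps_sd Residual SD on the observation scale at the median arm
#'   size.
#' @param obs_scale Observation scale for survival proportions: `"logit"`
#'   (default), `"cloglog"` (`log(-log S)`), or `"identity"`.
#' @param rse_pct Optional named vector of relative standard errors (%)
#'   for `mu`, `sigm`, `theta_duration`, `theta_riluzole`; used when
#'   simulating parameter uncertainty directly from published estimates.
#' @return An object of class `os_params`.
#' @seealso [als_reference_params()] for the published final-model
#'   estimates.
#' @export
os_params <- function(mu, sigm, theta_duration = 0, theta_riluzole = 0,
                      duration_center = 17.8,
                      eta_sd_mu = 0, eta_sd_sigm = 0, eps_sd = 0,
                      obs_scale = c("logit", "cloglog", "identity"),
                      rse_pct = NULL) {
  obs_scale <- match.arg(obs_scale)
  stopifnot(is.finite(mu), mu > 0, is.finite(sigm), sigm > 0,
            eta_sd_mu >= 0, eta_sd_sigm >= 0, eps_sd >= 0)
  structure(list(
    hazard = "lognormal",
    mu = mu, sigm = sigm,
    base = c(mu = mu, sigm = sigm),
    theta_duration = theta_duration, theta_riluzole = theta_riluzole,
    duration_center = duration_center,
    thetas = c(duration_months = theta_duration,
               riluzole_frac = theta_riluzole),
    centers = c(duration_months = duration_center, riluzole_frac = 0),
    eta_sd_mu = eta_sd_mu, eta_sd_sigm = eta_sd_sigm,
    eta_sd = c(mu = eta_sd_mu, sigm = eta_sd_sigm),
    eps_sd = eps_sd, obs_scale = obs_scale, rse_pct = rse_pct),
    class = "os_params")
}

# General survival-parameter container for non-lognormal base hazards used
# during base-model selection. `base` is the named positive parameter
# vector of the candidate family; random effects act multiplicatively on
# each base parameter.
os_params_general <- function(hazard, base, thetas = numeric(0),
                              centers = numeric(0), eta_sd = NULL,
                              eps_sd = 0, obs_scale = "logit",
                              rse_pct = NULL) {
  if (hazard == "lognormal") {
    return(os_params(mu = base[["mu"]], sigm = base[["sigm"]],
                     theta_duration = if ("duration_months" %in% names(thetas))
                       thetas[["duration_months"]] else 0,
                     theta_riluzole = if ("riluzole_frac" %in% names(thetas))
                       thetas[["riluzole_frac"]] else 0,
                     duration_center =
                       if ("duration_months" %in% names(centers))
                         centers[["duration_months"]] else 17.8,
                     eta_sd_mu = unname(eta_sd["mu"]),
                     eta_sd_sigm = unname(eta_sd["sigm"]),
                     eps_sd = eps_sd, obs_scale = obs_scale,
                     rse_pct = rse_pct))
  }
  if (is.null(eta_sd)) eta_sd <- rep(0, length(base))
  structure(list(hazard = hazard, base = base, thetas = thetas,
                 centers = centers, eta_sd = eta_sd, eps_sd = eps_sd,
                 obs_scale = obs_scale, rse_pct = rse_pct),
            class = "os_params")
}

#' Parameters of the sigmoid-Emax ALSFRS-R time course
#'
#' The typical mean change from baseline at time t (months) is
#' `-emax * t^gamma / (et50^gamma + t^gamma)`: zero at baseline,
#' monotone decline saturating at `-emax`. `et50` is the time to reach
#' half the maximal decline; `gamma` controls sigmoidicity. Study-level
#' random effects act multiplicatively on `emax` and `gamma`; their SDs
#' are CVs (fractions). The residual SD `eps_sd` is in ALSFRS-R points at
#' the corpus-median arm size (75), scaled by `sqrt(75 / n)` for an arm
#' of size n.
#'
#' @param emax Positive maximal decline magnitude, points (at most 48).
#' @param et50 Positive time to half-maximal decline, months.
#' @param gamma Positive shape (sigmoidicity) parameter.
#' @param eta_sd_emax,eta_sd_gamma Between-study CVs (fractions).
#' @param eps_sd Residual SD, points, at the median arm size.
#' @param rse_pct Optional named RSE (%) vector for `emax`, `et50`,
#'   `gamma`.
#' @return An object of class `emax_params`.
#' @export
emax_params <- function(emax, et50, gamma,
                        eta_sd_emax = 0, eta_sd_gamma = 0, eps_sd = 0,
                        rse_pct = NULL) {
  stopifnot(is.finite(emax), emax > 0, emax <= 48,
            is.finite(et50), et50 > 0, is.finite(gamma), gamma > 0,
            eta_sd_emax >= 0, eta_sd_gamma >= 0, eps_sd >= 0)
  structure(list(emax = emax, et50 = et50, gamma = gamma,
                 base = c(emax = emax, et50 = et50, gamma = gamma),
                 thetas = numeric(0), centers = numeric(0),
                 eta_sd_emax = eta_sd_emax, eta_sd_gamma = eta_sd_gamma,
                 eta_sd = c(emax = eta_sd_emax, gamma = eta_sd_gamma),
                 eps_sd = eps_sd, rse_pct = rse_pct),
            class = "emax_params")
}

#' Published final-model parameter estimates
#'
#' The final-model point estimates (with their relative standard errors)
#' of the historical ALS placebo meta-analysis: the log-normal-hazard OS
#' model with disease-duration and riluzole covariates, and the
#' sigmoid-Emax ALSFRS-R model. These serve as reference values for
#' simulation, as defaults of the synthetic-corpus generator, and as the
#' historical model in external-control and borrowing applications.
#'
#' @param endpoint `"OS"` or `"ALSFRS"`.
#' @return An [os_params()] or [emax_params()] object with `rse_pct` set.
#' @export
#' @examples
#' p <- als_reference_params("ALSFRS")
#' typical_change(c(12, 24, 48), p)
als_reference_params <- function(endpoint = c("OS", "ALSFRS")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "OS") {
    os_params(mu = 3.04, sigm = 0.916,
              theta_duration = 0.0317, theta_riluzole = -0.228,
              duration_center = 17.8,
              eta_sd_mu = 0.0720, eta_sd_sigm = 0.252,
              eps_sd = 0.693, obs_scale = "logit",
              rse_pct = c(mu = 2.80, sigm = 5.80,
                          theta_duration = 28.3, theta_riluzole = 57.5,
                          eta_sd_mu = 19.4, eta_sd_sigm = 15.6,
                          eps_sd = 17.2))
  } else {
    emax_params(emax = 26.2, et50 = 17.5, gamma = 1.2,
                eta_sd_emax = 0.258, eta_sd_gamma = 0.122, eps_sd = 4.00,
                rse_pct = c(emax = 7.0, et50 = 4.4, gamma = 5.8,
                            eta_sd_emax = 18.0, eta_sd_gamma = 20.0,
                            eps_sd = 14.9))
  }
}

#' @export
print.os_params <- function(x, ...) {
  cat(sprintf("Survival model (%s base hazard, obs scale %s)\n",
              x$hazard, x$obs_scale))
  cat("  base:", paste(sprintf("%s = %.4g", names(x$base), x$base),
                       collapse = ", "), "\n")
  if (length(x$thetas))
    cat("  log-hazard coefficients:",
        paste(sprintf("%s = %.4g (center %.4g)", names(x$thetas), x$thetas,
                      x$centers[names(x$thetas)]), collapse = ", "), "\n")
  cat(sprintf("  between-study CV: %s; residual SD %.4g\n",
              paste(sprintf("%s %.1f%%", names(x$eta_sd), 100 * x$eta_sd),
                    collapse = ", "), x$eps_sd))
  invisible(x)
}

#' @export
print.emax_params <- function(x, ...) {
  cat("Sigmoid-Emax ALSFRS-R model\n")
  cat(sprintf("  Emax = %.4g points, ET50 = %.4g months, gamma = %.4g\n",
              x$emax, x$et50, x$gamma))
  cat(sprintf("  between-study CV: Emax %.1f%%, gamma %.1f%%; residual SD %.4g points\n",
              100 * x$eta_sd_emax, 100 * x$eta_sd_gamma, x$eps_sd))
  invisible(x)
}

#' Serialize model parameters to flat JSON
#'
#' @param params An `os_params` or `emax_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  if (inherits(params, "os_params")) {
    if (params$hazard != "lognormal")
      stop("only lognormal OS parameter sets are serialized")
    x <- list(model = "os",
              mu = params$mu, sigm = params$sigm,
              theta_duration = params$theta_duration,
              theta_riluzole = params$theta_riluzole,
              duration_center = params$duration_center,
              eta_sd_mu = params$eta_sd_mu, eta_sd_sigm = params$eta_sd_sigm,
              eps_sd = params$eps_sd, obs_scale = params$obs_scale)
  } else if (inherits(params, "emax_params")) {
    x <- list(model = "emax",
              emax = params$emax, et50 = params$et50, gamma = params$gamma,
              eta_sd_emax = params$eta_sd_emax,
              eta_sd_gamma = params$eta_sd_gamma, eps_sd = params$eps_sd)
  } else stop("unsupported parameter object")
  if (!is.null(params$rse_pct)) x$rse_pct <- as.list(params$rse_pct)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read model parameters from flat JSON
#'
#' @param path Path written by [write_params()].
#' @return An `os_params` or `emax_params` object.
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rse <- if (!is.null(x$rse_pct)) unlist(x$rse_pct) else NULL
  if (identical(x$model, "os")) {
    os_params(mu = x$mu, sigm = x$sigm,
              theta_duration = x$theta_duration,
              theta_riluzole = x$theta_riluzole,
              duration_center = x$duration_center,
              eta_sd_mu = x$eta_sd_mu, eta_sd_sigm = x$eta_sd_sigm,
              eps_sd = x$eps_sd, obs_scale = x$obs_scale, rse_pct = rse)
  } else if (identical(x$model, "emax")) {
    emax_params(emax = x$emax, et50 = x$et50, gamma = x$gamma,
                eta_sd_emax = x$eta_sd_emax, eta_sd_gamma = x$eta_sd_gamma,
                eps_sd = x$eps_sd, rse_pct = rse)
  } else stop("unrecognized parameter file")
}
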