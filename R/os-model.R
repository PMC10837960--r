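# Base survival families available for the OS model. All parameters are
# positive; study random effects act multiplicatively on each.
base_hazard_pars <- function(hazard) {
  switch(hazard,
         lognormal = c("mu", "sigm"),
         weibull = c("scale", "shape"),
         loglogistic = c("scale", "shape"),
         exponential = "rate",
         stop("unknown base hazard: ", hazard))
}

# S0(t) for a base family; `pars` is a named list/vector of per-observation
# parameter values (already carrying any study random effect).
base_survival <- function(hazard, t, pars) {
  switch(hazard,
         lognormal = {
           s <- ifelse(t <= 0, 1, 1 - stats::pnorm((log(pmax(t, 1e-300)) -
                                                      pars[["mu"]]) /
                                                     pars[["sigm"]]))
           s
         },
         weibull = exp(-(t / pars[["scale"]])^pars[["shape"]]),
         loglogistic = 1 / (1 + (t / pars[["scale"]])^pars[["shape"]]),
         exponential = exp(-pars[["rate"]] * t),
         stop("unknown base hazard: ", hazard))
}

# Observation-scale transforms for survival proportions. The cloglog
# variant is log(-log S), monotone decreasing in S, so proportional
# hazards shifts it additively.
link_surv <- function(s, scale) {
  switch(scale,
         identity = s,
         logit = stats::qlogis(s),
         cloglog = log(-log(s)),
         stop("unknown observation scale: ", scale))
}

unlink_surv <- function(y, scale) {
  switch(scale,
         identity = y,
         logit = stats::plogis(y),
         cloglog = exp(-exp(y)),
         stop("unknown observation scale: ", scale))
}

clip_surv <- function(s, lo = 1e-9, hi = 1 - 1e-9) pmin(pmax(s, lo), hi)

#' Log hazard-ratio multiplier for a covariate profile
#'
#' The proportional-hazards linear predictor: each covariate coefficient
#' times the (centered) covariate value. Under the default model this is
#' `theta_duration * (duration - duration_center) +
#' theta_riluzole * riluzole_frac`.
#'
#' @param cov A [covariate_profile()].
#' @param params An [os_params()] object.
#' @return The log hazard multiplier (a single number).
#' @export
#' @examples
#' p <- als_reference_params("OS")
#' log_hazard_multiplier(covariate_profile(17.8, 0), p)  # 0
log_hazard_multiplier <- function(cov, params) {
  stopifnot(inherits(cov, "covariate_profile"),
            inherits(params, "os_params"))
  if (!length(params$thetas)) return(0)
  x <- vapply(names(params$thetas), function(nm) {
    v <- cov[[nm]]
    if (is.null(v) || is.na(v))
      stop("covariate profile is missing required covariate: ", nm)
    as.numeric(v)
  }, numeric(1))
  sum(params$thetas * (x - params$centers[names(params$thetas)]))
}

#' Survival function of the OS model
#'
#' `S(t) = S0(t)^exp(lp)` where `S0` is the base survival with
#' study-specific parameters `base * exp(eta)` and `lp` is the
#' proportional-hazards linear predictor of the covariate profile.
#'
#' @param t Nonnegative times, months (vectorized).
#' @param cov A [covariate_profile()].
#' @param params An [os_params()] object.
#' @param eta Study random effects on the base parameters (log scale);
#'   defaults to zero (the typical study).
#' @return Survival probabilities in (0, 1\].
#' @export
os_survival <- function(t, cov, params, eta = NULL) {
  stopifnot(inherits(params, "os_params"))
  if (any(t < 0)) stop("t must be nonnegative")
  pnames <- names(params$base)
  if (is.null(eta)) eta <- rep(0, length(pnames))
  pars_i <- as.list(params$base * exp(eta))
  names(pars_i) <- pnames
  hr <- exp(log_hazard_multiplier(cov, params))
  base_survival(params$hazard, t, pars_i)^hr
}

#' Hazard function of the OS model
#'
#' Base-family hazard times the covariate hazard ratio. Provided mainly
#' for numerical cross-checks of the survival function.
#'
#' @inheritParams os_survival
#' @return Hazard values, per month.
#' @export
os_hazard <- function(t, cov, params, eta = NULL) {
  stopifnot(inherits(params, "os_params"))
  if (any(t <= 0)) stop("t must be positive for the hazard")
  pnames <- names(params$base)
  if (is.null(eta)) eta <- rep(0, length(pnames))
  p <- params$base * exp(eta)
  h0 <- switch(params$hazard,
               lognormal = stats::dlnorm(t, p[["mu"]], p[["sigm"]]) /
                 (1 - stats::plnorm(t, p[["mu"]], p[["sigm"]])),
               weibull = (p[["shape"]] / p[["scale"]]) *
                 (t / p[["scale"]])^(p[["shape"]] - 1),
               loglogistic = {
                 u <- (t / p[["scale"]])^p[["shape"]]
                 (p[["shape"]] / t) * u / (1 + u)
               },
               exponential = rep(p[["rate"]], length(t)))
  h0 * exp(log_hazard_multiplier(cov, params))
}

#' Median overall survival implied by the model
#'
#' Solves `S(t) = 0.5` by bracketing and Brent's method on
#' (1e-6, 600\] months, to 1e-6 months.
#'
#' @inheritParams os_survival
#' @return Median OS in months.
#' @export
#' @examples
#' p <- als_reference_params("OS")
#' median_os(covariate_profile(17.8, 0), p)  # exp(3.04) ~ 20.9 months
median_os <- function(cov, params, eta = NULL, horizon = 600) {
  f <- function(t) os_survival(t, cov, params, eta) - 0.5
  if (f(horizon) > 0)
    stop("median beyond horizon: S(", horizon, ") > 0.5")
  stats::uniroot(f, lower = 1e-6, upper = horizon, tol = 1e-9)$root
}

#' Predicted survival series for an arm, on an observation scale
#'
#' Evaluates the model survival at the arm's observation times and maps
#' it to the requested scale (the scale on which residuals are modeled).
#' Survival values numerically equal to 1 (or 0) are clipped to
#' `1 - 1e-9` (`1e-9`) before a logit or cloglog transform, with a
#' warning.
#'
#' @param arm A [study_arm()] with a non-empty OS series.
#' @param params An [os_params()] object.
#' @param eta Study random effects (defaults to zero).
#' @param scale Observation scale; defaults to the scale configured in
#'   `params`.
#' @return Numeric vector of predictions at `arm$os_series$time_months`.
#' @export
predict_surv_series <- function(arm, params, eta = NULL, scale = NULL) {
  stopifnot(inherits(arm, "study_arm"))
  if (nrow(arm$os_series) == 0L) stop("arm has no OS series")
  if (is.null(scale)) scale <- params$obs_scale
  s <- os_survival(arm$os_series$time_months, arm$covariates, params, eta)
  if (scale != "identity" && any(s >= 1 - 1e-9 | s <= 1e-9)) {
    warning("survival at boundary clipped before ", scale, " transform")
    s <- clip_surv(s)
  }
  link_surv(s, scale)
}
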