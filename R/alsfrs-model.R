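#' Typical ALSFRS-R change from baseline under the sigmoid-Emax model
#'
#' Returns `-E * t^g / (et50^g + t^g)` with `E = emax * exp(eta_emax)`
#' and `g = gamma * exp(eta_gamma)`: zero at t = 0, monotone decline,
#' approaching `-E` as t grows. Declines are negative by convention;
#' `emax` stores the positive magnitude.
#'
#' @param t Nonnegative times, months (vectorized).
#' @param params An [emax_params()] object.
#' @param eta Length-2 study effects on `(emax, gamma)`; defaults to
#'   zero.
#' @return Mean ALSFRS-R change from baseline, points (non-positive).
#' @export
#' @examples
#' typical_change(12, als_reference_params("ALSFRS"))  # about -10.2
typical_change <- function(t, params, eta = c(0, 0)) {
  stopifnot(inherits(params, "emax_params"))
  if (any(t < 0)) stop("t must be nonnegative")
  e <- params$emax * exp(eta[1L])
  g <- params$gamma * exp(eta[2L])
  tg <- t^g
  -e * tg / (params$et50^g + tg)
}

#' Fraction of the maximal decline reached by time t
#'
#' `t^g / (et50^g + t^g)`, in \[0, 1): 0.5 exactly at `t = et50`.
#'
#' @inheritParams typical_change
#' @return Fractions in \[0, 1).
#' @export
#' @examples
#' fraction_of_max(c(3, 48), als_reference_params("ALSFRS"))
fraction_of_max <- function(t, params) {
  stopifnot(inherits(params, "emax_params"))
  if (any(t < 0)) stop("t must be nonnegative")
  tg <- t^params$gamma
  tg / (params$et50^params$gamma + tg)
}

#' Predicted score series for an arm
#'
#' Evaluates the sigmoid-Emax curve with the arm's study effects at the
#' arm's observation times.
#'
#' @param arm A [study_arm()] with a non-empty score series.
#' @param params An [emax_params()] object.
#' @param eta Length-2 study effects on `(emax, gamma)`.
#' @return Numeric vector of predicted mean changes, points.
#' @export
predict_score_series <- function(arm, params, eta = c(0, 0)) {
  stopifnot(inherits(arm, "study_arm"))
  if (nrow(arm$score_series) == 0L) stop("arm has no score series")
  typical_change(arm$score_series$time_months, params, eta)
}
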