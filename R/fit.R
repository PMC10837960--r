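default_cov_center <- function(cov) {
  # fractions and flags enter uncentered (like the riluzole term of the
  # final model); other continuous covariates are centered at the corpus
  # median at prep time
  if (cov %in% c("riluzole_frac", "male_frac", "bulbar_frac",
                 "basic_treatment")) 0 else "median"
}

default_covariates <- function(endpoint) {
  if (endpoint == "OS")
    list(list(cov = "duration_months", center = 17.8, on = "hazard"),
         list(cov = "riluzole_frac", center = 0, on = "hazard"))
  else list()
}

normalize_covariates <- function(covariates, endpoint) {
  if (is.null(covariates)) return(default_covariates(endpoint))
  lapply(covariates, function(cc) {
    if (is.character(cc)) cc <- list(cov = cc)
    if (is.null(cc$center)) cc$center <- default_cov_center(cc$cov)
    if (is.null(cc$on))
      cc$on <- if (endpoint == "OS") "hazard" else
        stop("ALSFRS covariates need a target parameter (on=)")
    cc
  })
}

params_to_phi <- function(params, prep, min_eta = 1e-3) {
  base <- params$base[prep$base_names]
  th <- rep(0, length(prep$theta_names))
  names(th) <- prep$theta_names
  common <- intersect(names(params$thetas), prep$theta_names)
  th[common] <- params$thetas[common]
  om <- pmax(params$eta_sd, min_eta)
  if (prep$endpoint == "ALSFRS") om <- om[c("emax", "gamma")]
  c(log(base), th, log(om), log(max(params$eps_sd, 1e-3)))
}

phi_to_params <- function(phi, prep, rse_pct = NULL) {
  sp <- split_phi(phi, prep)
  if (prep$endpoint == "OS") {
    os_params_general(prep$hazard, sp$base,
                      thetas = sp$thetas, centers = prep$centers,
                      eta_sd = stats::setNames(sp$om, prep$base_names),
                      eps_sd = sp$eps, obs_scale = prep$obs_scale,
                      rse_pct = rse_pct)
  } else {
    p <- emax_params(emax = min(sp$base[["emax"]], 48),
                     et50 = sp$base[["et50"]],
                     gamma = sp$base[["gamma"]],
                     eta_sd_emax = sp$om[1L], eta_sd_gamma = sp$om[2L],
                     eps_sd = sp$eps, rse_pct = rse_pct)
    # carry any covariate effects on log parameters
    p$thetas <- sp$thetas
    p$centers <- prep$centers
    p$theta_on <- prep$theta_on
    p
  }
}

phi_names <- function(prep) {
  c(prep$base_names,
    if (length(prep$theta_names)) paste0("theta_", prep$theta_names),
    paste0("eta_sd_", if (prep$endpoint == "OS") prep$base_names
           else c("emax", "gamma")),
    "eps_sd")
}

# crude data-driven starting values on the estimation scale
start_phi <- function(prep) {
  if (prep$endpoint == "OS") {
    # per-arm time at which the observed series crosses 0.5
    t50 <- vapply(seq_len(prep$n_arms), function(i) {
      sel <- prep$arm == i
      tt <- prep$t[sel]; ss <- prep$y_nat[sel]
      if (all(ss > 0.5)) return(NA_real_)
      j <- which(ss <= 0.5)[1L]
      if (j == 1L) tt[1L]
      else stats::approx(ss[c(j - 1L, j)], tt[c(j - 1L, j)], 0.5)$y
    }, numeric(1))
    m50 <- stats::median(t50, na.rm = TRUE)
    if (!is.finite(m50)) m50 <- stats::median(prep$t) * 1.5
    base0 <- switch(prep$hazard,
                    lognormal = c(mu = log(m50), sigm = 0.9),
                    weibull = c(scale = m50 / log(2), shape = 1.1),
                    loglogistic = c(scale = m50, shape = 1.5),
                    exponential = c(rate = log(2) / m50))
    eps0 <- if (prep$obs_scale == "identity") 0.1 else 0.5
    c(log(base0), rep(0, length(prep$theta_names)),
      rep(log(0.15), prep$q), log(eps0))
  } else {
    emax0 <- min(40, 1.3 * max(abs(prep$y_nat)) + 1)
    et0 <- min(40, max(3, stats::median(prep$t)))
    c(log(c(emax0, et0, 1.1)), rep(0, length(prep$theta_names)),
      log(c(0.2, 0.15)), log(2))
  }
}

phi_bounds <- function(prep) {
  np <- prep$n_par
  lower <- rep(-10, np); upper <- rep(10, np)
  if (prep$endpoint == "ALSFRS") upper[1L] <- log(48)  # Emax is a score
  lower[prep$it] <- -5; upper[prep$it] <- 5
  lower[prep$ie] <- log(1e-3); upper[prep$ie] <- log(5)
  lower[prep$is_] <- log(1e-4); upper[prep$is_] <- log(50)
  list(lower = lower, upper = upper)
}

#' Fit the placebo disease-course model to an aggregate corpus
#'
#' Maximizes the Laplace-approximated marginal likelihood of a nonlinear
#' mixed-effects model for arm-level aggregate data: observations on the
#' configured scale are normal around structural predictions given
#' study-level random effects, the random effects are normal on the log
#' parameters (multiplicative), and the residual SD of an arm of size n
#' is scaled by `sqrt(75 / n)`. For `endpoint = "OS"` the structural
#' model is a parametric survival curve (default log-normal base hazard)
#' with proportional-hazards covariates; for `endpoint = "ALSFRS"` it is
#' the sigmoid-Emax time course with no covariates by default.
#'
#' Optimization runs `n_starts` times (the first from a data-driven
#' start, the rest jittered) and keeps the best converged solution.
#' Standard errors come from the observed-information Hessian of the
#' objective; if that Hessian is singular the SEs are `NA`.
#'
#' @param corpus An [als_corpus()].
#' @param endpoint `"OS"` or `"ALSFRS"`.
#' @param base_hazard Base survival family for OS: `"lognormal"`
#'   (default), `"weibull"`, `"loglogistic"` or `"exponential"`.
#' @param covariates `NULL` for the endpoint default (duration + riluzole
#'   on the OS hazard; none for ALSFRS), or a list of
#'   `list(cov =, center =, on =)` entries. `center = "median"` centers
#'   at the corpus median; `on` is `"hazard"` (OS) or one of
#'   `"emax"`, `"et50"`, `"gamma"` (ALSFRS).
#' @param obs_scale Observation scale for OS proportions (`"logit"`,
#'   `"cloglog"`, `"identity"`).
#' @param start Optional starting values: a parameter object or an
#'   estimation-scale numeric vector.
#' @param n_starts Number of optimization starts (default 5).
#' @param seed Optional seed for the start jitter.
#' @param compute_se Compute the observed-information SEs (default TRUE;
#'   skipped during bootstrap replicates for speed).
#' @param weighting Residual weighting: `"size"` (SD scaled by
#'   `sqrt(75/n)`, the default) or `"se"` (score endpoint only: per-point
#'   reported SEs, normalized to their median).
#' @param min_arms Minimum number of arms required (default 3).
#' @param control Passed to [stats::nlminb()] (defaults:
#'   `rel.tol = 1e-8`, `iter.max = 400`).
#' @return An object of class `mbma_fit` with components `params` (the
#'   point estimates as an [os_params()]/[emax_params()] object),
#'   `estimates` (parameter table with SEs and RSEs), `ofv`
#'   (-2 log marginal likelihood), `eb` (empirical-Bayes study effects),
#'   `converged`, `n_arms`, and the data preparation needed by the
#'   diagnostic and simulation tools.
#' @seealso [select_base_hazard()], [covariate_search()],
#'   [mbma_bootstrap()], [gof()], [vpc()], [simulate_typical()]
#' @export
mbma_fit <- function(corpus, endpoint = c("OS", "ALSFRS"),
                     base_hazard = c("lognormal", "weibull", "loglogistic",
                                     "exponential"),
                     covariates = NULL, obs_scale = "logit",
                     start = NULL, n_starts = 5L, seed = NULL,
                     compute_se = TRUE, weighting = c("size", "se"),
                     min_arms = 3L, control = list()) {
  endpoint <- match.arg(endpoint)
  base_hazard <- match.arg(base_hazard)
  weighting <- match.arg(weighting)
  covariates <- normalize_covariates(covariates, endpoint)
  prep <- prep_likelihood(corpus, endpoint, base_hazard, covariates,
                          obs_scale, weighting)
  if (prep$n_arms < min_arms)
    stop("need at least ", min_arms, " arms with endpoint ", endpoint)
  ctrl <- utils::modifyList(list(rel.tol = 1e-8, iter.max = 400L,
                                 eval.max = 1200L), control)
  phi0 <- if (is.null(start)) start_phi(prep)
  else if (is.numeric(start)) start
  else params_to_phi(start, prep)
  bounds <- phi_bounds(prep)
  phi0 <- pmin(pmax(phi0, bounds$lower), bounds$upper)
  if (!is.null(seed)) set.seed(seed)
  starts <- list(phi0)
  if (n_starts > 1L)
    for (k in seq_len(n_starts - 1L))
      starts[[k + 1L]] <- pmin(pmax(phi0 + stats::rnorm(length(phi0), 0, 0.1),
                                    bounds$lower), bounds$upper)
  state <- new.env(parent = emptyenv())
  obj <- function(phi) ofv_laplace(phi, prep, state)
  best <- NULL
  for (s in starts) {
    state$eta <- NULL
    res <- tryCatch(
      stats::nlminb(s, obj, lower = bounds$lower, upper = bounds$upper,
                    control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    res$conv_ok <- res$convergence == 0 && is.finite(res$objective) &&
      res$objective < 1e9
    if (is.null(best) ||
        (res$conv_ok && !best$conv_ok) ||
        (res$conv_ok == best$conv_ok && res$objective < best$objective))
      best <- res
  }
  if (is.null(best)) stop("optimization failed from every start")
  phi_hat <- best$par
  if (!best$conv_ok && is.finite(best$objective) && best$objective < 1e9) {
    # nlminb can flag "false convergence" at a variance boundary even at
    # the optimum; confirm by restarting once: if the solution barely
    # moves and barely improves, accept it as converged
    for (restart in 1:3) {
      state$eta <- NULL
      res2 <- tryCatch(
        stats::nlminb(phi_hat, obj, lower = bounds$lower,
                      upper = bounds$upper, control = ctrl),
        error = function(e) NULL)
      if (is.null(res2) || !is.finite(res2$objective) ||
          res2$objective > best$objective + 1e-4) break
      moved <- max(abs(res2$par - phi_hat))
      improved <- best$objective - res2$objective
      if (improved > 0) {
        phi_hat <- res2$par
        best$objective <- res2$objective
      }
      if (res2$convergence == 0 || (moved < 0.01 && abs(improved) < 0.1)) {
        best$conv_ok <- TRUE
        break
      }
    }
  }
  state$eta <- NULL
  ofv <- obj(phi_hat)
  # empirical-Bayes modes and conditional precision at the solution
  sp <- split_phi(phi_hat, prep)
  im <- inner_modes(prep, sp$base, sp$thetas, sp$om, sp$eps)
  hs <- if (sum(im$act) > 0L)
    arm_hessians(prep, sp$base, sp$thetas, sp$om, sp$eps, im$eta, im$act)
  else NULL
  se_phi <- rep(NA_real_, prep$n_par)
  vcov_phi <- matrix(NA_real_, prep$n_par, prep$n_par)
  if (compute_se) {
    H <- tryCatch(pracma::hessian(obj, phi_hat), error = function(e) NULL)
    if (!is.null(H) && all(is.finite(H))) {
      info <- (H + t(H)) / 4  # observed information: Hessian(-logLik) = H/2

      cv <- tryCatch(solve(info), error = function(e) NULL)
      if (!is.null(cv)) {
        d <- diag(cv)
        se_phi <- suppressWarnings(ifelse(d > 0, sqrt(d), NA_real_))
        vcov_phi <- cv
      } else warning("singular information matrix; SEs reported NA")
    } else if (compute_se) warning("Hessian computation failed; SEs NA")
  }
  nm <- phi_names(prep)
  est_nat <- phi_hat
  se_nat <- se_phi
  logidx <- c(prep$ib, prep$ie, prep$is_)
  est_nat[logidx] <- exp(phi_hat[logidx])
  se_nat[logidx] <- est_nat[logidx] * se_phi[logidx]
  estimates <- data.frame(parameter = nm, estimate = est_nat, se = se_nat,
                          rse_pct = 100 * abs(se_nat / est_nat),
                          stringsAsFactors = FALSE)
  rownames(estimates) <- NULL
  rse <- stats::setNames(estimates$rse_pct, nm)
  params <- phi_to_params(phi_hat, prep, rse_pct = rse)
  eb <- build_eb_table(prep, sp, im, hs)
  structure(list(params = params, endpoint = endpoint,
                 hazard = if (endpoint == "OS") base_hazard else NA,
                 obs_scale = obs_scale,
                 estimates = estimates, phi = stats::setNames(phi_hat, nm),
                 se_phi = stats::setNames(se_phi, nm), vcov_phi = vcov_phi,
                 ofv = ofv, logLik = -ofv / 2,
                 converged = isTRUE(best$conv_ok),
                 n_arms = prep$n_arms, n_obs = prep$n_obs,
                 n_par = prep$n_par, weighting = weighting,
                 eb = eb, prep = prep, corpus = corpus,
                 covariates = covariates, call = match.call()),
            class = "mbma_fit")
}

build_eb_table <- function(prep, sp, im, hs) {
  q <- prep$q
  enames <- if (prep$endpoint == "OS") prep$base_names else c("emax", "gamma")
  eb <- data.frame(study_id = prep$study_ids, n = prep$n_arm,
                   n_obs = prep$n_per, stringsAsFactors = FALSE)
  act <- im$act
  cond_sd <- matrix(NA_real_, prep$n_arms, q)
  if (!is.null(hs)) {
    ai <- which(act)
    if (sum(act) == 1L) {
      cond_sd[, ai] <- sqrt(1 / hs$H11)
    } else {
      det <- hs$H11 * hs$H22 - hs$H12^2
      cond_sd[, ai[1L]] <- sqrt(hs$H22 / det)
      cond_sd[, ai[2L]] <- sqrt(hs$H11 / det)
    }
  }
  # inactive dimensions: prior mode 0 with prior SD
  for (k in seq_len(q)) if (!act[k]) cond_sd[, k] <- sp$om[k]
  base_idx <- if (prep$endpoint == "OS") seq_len(prep$n_base) else c(1L, 3L)
  for (k in seq_len(q)) {
    eb[[paste0("eta_", enames[k])]] <- im$eta[, k]
    eb[[paste0("cond_sd_", enames[k])]] <- cond_sd[, k]
    pv <- sp$base[base_idx[k]] * exp(im$eta[, k])
    eb[[enames[k]]] <- pv
    eb[[paste0("se_", enames[k])]] <- pv * cond_sd[, k]
  }
  eb
}
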