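# Marginal-likelihood machinery for the aggregate-data nonlinear
# mixed-effects models. Per arm i with observations y_ij on the configured
# scale:
#   y_ij | eta_i ~ N(f(t_ij; psi, eta_i), (w_i * eps)^2),  w_i = sqrt(75/n_i)
#   eta_i ~ N(0, diag(om^2))   (multiplicative lognormal on parameters)
# The marginal likelihood integrates eta out with a Laplace approximation
# at the per-arm posterior mode; modes are found by damped Gauss-Newton,
# vectorized across arms. An adaptive Gauss-Hermite version exists as a
# numerical cross-check on small corpora.

MEDIAN_ARM_N <- 75  # corpus-median arm size anchoring the residual SD

# Assemble the flat observation structure the engine works on.
# covariates: list of list(cov=, center=, on=) entries; `on` is "hazard"
# for OS or one of emax/et50/gamma for ALSFRS. Arms missing a required
# covariate are dropped (count reported via message).
prep_likelihood <- function(corpus, endpoint, hazard = "lognormal",
                            covariates = list(), obs_scale = "logit",
                            weighting = "size") {
  stopifnot(inherits(corpus, "als_corpus"))
  endpoint <- match.arg(endpoint, c("OS", "ALSFRS"))
  arms <- Filter(function(a) {
    if (endpoint == "OS") nrow(a$os_series) > 0 else nrow(a$score_series) > 0
  }, corpus$arms)
  if (length(covariates)) {
    need <- vapply(covariates, `[[`, character(1), "cov")
    keep <- vapply(arms, function(a)
      all(!is.na(unlist(a$covariates[need]))), logical(1))
    if (any(!keep))
      message(sum(!keep), " arm(s) dropped: missing covariate(s) ",
              paste(need, collapse = ", "))
    arms <- arms[keep]
  }
  if (length(arms) < 1L)
    stop("no arms with endpoint ", endpoint)
  n_arms <- length(arms)
  series <- lapply(arms, function(a)
    if (endpoint == "OS") a$os_series else a$score_series)
  n_per <- vapply(series, nrow, integer(1))
  arm_idx <- rep(seq_len(n_arms), n_per)
  t_all <- unlist(lapply(series, `[[`, "time_months"), use.names = FALSE)
  y_nat <- if (endpoint == "OS")
    unlist(lapply(series, `[[`, "surv_prob"), use.names = FALSE)
  else unlist(lapply(series, `[[`, "mean_change"), use.names = FALSE)
  n_arm <- vapply(arms, `[[`, numeric(1), "n")
  y <- if (endpoint == "OS") link_surv(clip_surv(y_nat), obs_scale) else y_nat
  w <- sqrt(MEDIAN_ARM_N / n_arm)[arm_idx]
  if (weighting == "se") {
    if (endpoint != "ALSFRS")
      stop("SE weighting is only available for the score endpoint")
    se_all <- unlist(lapply(series, `[[`, "se"), use.names = FALSE)
    if (any(is.na(se_all)))
      stop("SE weighting requires a reported SE for every score point")
    # normalize so eps_sd keeps the scale of the median reported SE
    w <- se_all / stats::median(se_all)
  }
  theta_names <- character(0); theta_on <- character(0)
  X <- matrix(0, n_arms, 0)
  centers <- numeric(0)
  if (length(covariates)) {
    X <- sapply(covariates, function(cc) {
      x <- vapply(arms, function(a) as.numeric(a$covariates[[cc$cov]]),
                  numeric(1))
      ctr <- cc$center
      if (identical(ctr, "median")) ctr <- stats::median(x)
      x - ctr
    })
    X <- matrix(X, nrow = n_arms)
    theta_names <- vapply(covariates, `[[`, character(1), "cov")
    theta_on <- vapply(covariates, function(cc)
      if (is.null(cc$on)) "hazard" else cc$on, character(1))
    centers <- vapply(covariates, function(cc) {
      if (identical(cc$center, "median")) {
        x <- vapply(arms, function(a) as.numeric(a$covariates[[cc$cov]]),
                    numeric(1))
        stats::median(x)
      } else as.numeric(cc$center)
    }, numeric(1))
    names(centers) <- theta_names
  }
  base_names <- if (endpoint == "OS") base_hazard_pars(hazard)
  else c("emax", "et50", "gamma")
  q <- if (endpoint == "OS") length(base_names) else 2L
  n_base <- length(base_names)
  n_theta <- length(theta_names)
  ib <- seq_len(n_base)
  it <- if (n_theta) n_base + seq_len(n_theta) else integer(0)
  ie <- n_base + n_theta + seq_len(q)
  is_ <- n_base + n_theta + q + 1L
  list(endpoint = endpoint, hazard = hazard, obs_scale = obs_scale,
       t = t_all, logt = log(pmax(t_all, 1e-300)),
       ends = cumsum(n_per),
       y = y, y_nat = y_nat, arm = arm_idx,
       w = w, weighting = weighting,
       n_obs = length(t_all), n_arms = n_arms,
       study_ids = vapply(arms, `[[`, character(1), "study_id"),
       n_arm = n_arm, n_per = n_per, arms = arms,
       X = X, theta_names = theta_names, theta_on = theta_on,
       centers = centers,
       base_names = base_names, n_base = n_base, q = q,
       ib = ib, it = it, ie = ie, is_ = is_,
       n_par = is_)
}

split_phi <- function(phi, prep) {
  list(base = stats::setNames(exp(phi[prep$ib]), prep$base_names),
       thetas = stats::setNames(phi[prep$it], prep$theta_names),
       om = exp(phi[prep$ie]),
       eps = exp(phi[prep$is_]))
}

# Structural predictions on the observation scale for all observations,
# given base parameters, covariate coefficients and an n_arms x q matrix
# of study effects.
struct_pred <- function(prep, base, thetas, eta) {
  if (prep$endpoint == "OS") {
    barm <- matrix(base, prep$n_arms, prep$n_base, byrow = TRUE) * exp(eta)
    lp <- rep(0, prep$n_arms)
    if (length(thetas)) lp <- drop(prep$X %*% thetas)
    s <- if (prep$hazard == "lognormal") {
      # fast path: precomputed log times
      stats::pnorm((prep$logt - barm[prep$arm, 1L]) / barm[prep$arm, 2L],
                   lower.tail = FALSE)
    } else {
      pars <- lapply(seq_len(prep$n_base), function(k) barm[prep$arm, k])
      names(pars) <- prep$base_names
      base_survival(prep$hazard, prep$t, pars)
    }
    s <- s^exp(lp)[prep$arm]
    link_surv(clip_surv(s), prep$obs_scale)
  } else {
    parm <- matrix(base, prep$n_arms, 3L, byrow = TRUE)
    parm[, 1L] <- parm[, 1L] * exp(eta[, 1L])
    parm[, 3L] <- parm[, 3L] * exp(eta[, 2L])
    if (length(thetas)) {
      for (j in seq_along(thetas)) {
        k <- match(prep$theta_on[j], c("emax", "et50", "gamma"))
        parm[, k] <- parm[, k] * exp(thetas[j] * prep$X[, j])
      }
    }
    e <- parm[prep$arm, 1L]; et50 <- parm[prep$arm, 2L]
    g <- parm[prep$arm, 3L]
    tg <- prep$t^g
    -e * tg / (et50^g + tg)
  }
}

# Per-arm sums of a per-observation vector (observations are grouped and
# ordered by arm, so cumulative sums at the arm boundaries suffice).
arm_sum <- function(x, prep) {
  cs <- cumsum(x)[prep$ends]
  diff(c(0, cs))
}

# Penalized per-arm objective q_i(eta): negative joint log density of
# (y_i, eta_i) including all normalizing constants.
pen_obj_arms <- function(prep, base, thetas, om, eps, eta, act) {
  f <- struct_pred(prep, base, thetas, eta)
  r <- (prep$y - f) / (prep$w * eps)
  ss <- arm_sum(r^2, prep) / 2 +
    arm_sum(log(prep$w * eps) + 0.5 * log(2 * pi), prep)
  if (any(act)) {
    pen <- drop(eta[, act, drop = FALSE]^2 %*% (1 / (2 * om[act]^2))) +
      sum(log(om[act]) + 0.5 * log(2 * pi))
    ss <- ss + pen
  }
  ss
}

# Damped Gauss-Newton for the per-arm posterior modes, vectorized across
# arms. Dimensions with om below the threshold are pinned at zero.
inner_modes <- function(prep, base, thetas, om, eps, eta0 = NULL,
                        max_iter = 60L, tol = 1e-9) {
  q <- prep$q
  act <- om > 1e-8
  if (is.null(eta0)) eta0 <- matrix(0, prep$n_arms, q)
  eta <- eta0
  eta[, !act] <- 0
  qa <- sum(act)
  if (qa == 0L)
    return(list(eta = eta,
                qv = pen_obj_arms(prep, base, thetas, om, eps, eta, act),
                act = act))
  ai <- which(act)
  sd_obs <- prep$w * eps
  h <- 1e-5
  obj <- pen_obj_arms(prep, base, thetas, om, eps, eta, act)
  for (iter in seq_len(max_iter)) {
    f0 <- struct_pred(prep, base, thetas, eta)
    r0 <- (prep$y - f0) / sd_obs
    Jw <- matrix(0, prep$n_obs, qa)
    for (k in seq_len(qa)) {
      ep <- eta
      ep[, ai[k]] <- ep[, ai[k]] + h
      Jw[, k] <- -(struct_pred(prep, base, thetas, ep) - f0) / (h * sd_obs)
    }
    # per-arm gradient and GN Hessian of the penalized objective
    grad <- matrix(0, prep$n_arms, qa)
    for (k in seq_len(qa))
      grad[, k] <- arm_sum(r0 * Jw[, k], prep) + eta[, ai[k]] / om[ai[k]]^2
    delta <- matrix(0, prep$n_arms, qa)
    if (qa == 1L) {
      A <- arm_sum(Jw[, 1L]^2, prep) + 1 / om[ai]^2
      delta[, 1L] <- -grad[, 1L] / A
    } else {
      A11 <- arm_sum(Jw[, 1L]^2, prep) + 1 / om[ai[1L]]^2
      A22 <- arm_sum(Jw[, 2L]^2, prep) + 1 / om[ai[2L]]^2
      A12 <- arm_sum(Jw[, 1L] * Jw[, 2L], prep)
      det <- A11 * A22 - A12^2
      det[det < 1e-300] <- 1e-300
      delta[, 1L] <- -(A22 * grad[, 1L] - A12 * grad[, 2L]) / det
      delta[, 2L] <- -(A11 * grad[, 2L] - A12 * grad[, 1L]) / det
    }
    # damped update: halve per-arm steps until no arm worsens
    step <- rep(1, prep$n_arms)
    for (half in 1:8) {
      eta_new <- eta
      eta_new[, ai] <- eta[, ai] + delta * step
      obj_new <- pen_obj_arms(prep, base, thetas, om, eps, eta_new, act)
      worse <- obj_new > obj + 1e-12
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    if (any(worse)) {  # arms that never improved stay put this iteration
      step[worse] <- 0
      eta_new[, ai] <- eta[, ai] + delta * step
      obj_new <- pen_obj_arms(prep, base, thetas, om, eps, eta_new, act)
    }
    moved <- max(abs(delta * step))
    eta <- eta_new
    obj <- pmin(obj, obj_new)
    if (moved < tol) break
  }
  list(eta = eta, qv = obj, act = act)
}

# Per-arm Hessians of q_i at the mode, by central finite differences over
# the active dimensions. Returns log-determinants and the Hessian entries
# (for conditional SDs). Falls back to the Gauss-Newton approximation for
# arms where the FD Hessian is not positive definite.
arm_hessians <- function(prep, base, thetas, om, eps, eta, act, hh = 1e-3) {
  qa <- sum(act)
  ai <- which(act)
  p0 <- pen_obj_arms(prep, base, thetas, om, eps, eta, act)
  ev <- function(d1, d2 = 0, k1 = 1L, k2 = 2L) {
    ep <- eta
    ep[, ai[k1]] <- ep[, ai[k1]] + d1
    if (qa > 1L) ep[, ai[k2]] <- ep[, ai[k2]] + d2
    pen_obj_arms(prep, base, thetas, om, eps, ep, act)
  }
  if (qa == 1L) {
    H11 <- (ev(hh) - 2 * p0 + ev(-hh)) / hh^2
    bad <- !(H11 > 0) | !is.finite(H11)
    if (any(bad)) {
      gn <- gn_hessian(prep, base, thetas, om, eps, eta, act)
      H11[bad] <- gn$H11[bad]
    }
    return(list(logdet = log(H11), H11 = H11, H22 = NULL, H12 = NULL))
  }
  H11 <- (ev(hh, 0, 1L) - 2 * p0 + ev(-hh, 0, 1L)) / hh^2
  H22 <- (ev(hh, 0, 2L, 2L) - 2 * p0 + ev(-hh, 0, 2L, 2L)) / hh^2
  pp <- pen_obj_arms(prep, base, thetas, om, eps,
                     {e <- eta; e[, ai] <- e[, ai] + hh; e}, act)
  pm <- pen_obj_arms(prep, base, thetas, om, eps,
                     {e <- eta; e[, ai[1L]] <- e[, ai[1L]] + hh
                      e[, ai[2L]] <- e[, ai[2L]] - hh; e}, act)
  mp <- pen_obj_arms(prep, base, thetas, om, eps,
                     {e <- eta; e[, ai[1L]] <- e[, ai[1L]] - hh
                      e[, ai[2L]] <- e[, ai[2L]] + hh; e}, act)
  mm <- pen_obj_arms(prep, base, thetas, om, eps,
                     {e <- eta; e[, ai] <- e[, ai] - hh; e}, act)
  H12 <- (pp - pm - mp + mm) / (4 * hh^2)
  det <- H11 * H22 - H12^2
  bad <- !(det > 0 & H11 > 0) | !is.finite(det)
  if (any(bad)) {
    gn <- gn_hessian(prep, base, thetas, om, eps, eta, act)
    H11[bad] <- gn$H11[bad]; H22[bad] <- gn$H22[bad]
    H12[bad] <- gn$H12[bad]
    det <- H11 * H22 - H12^2
    det[det <= 0] <- 1e-300
  }
  list(logdet = log(det), H11 = H11, H22 = H22, H12 = H12)
}

gn_hessian <- function(prep, base, thetas, om, eps, eta, act, h = 1e-5) {
  qa <- sum(act)
  ai <- which(act)
  sd_obs <- prep$w * eps
  f0 <- struct_pred(prep, base, thetas, eta)
  Jw <- matrix(0, prep$n_obs, qa)
  for (k in seq_len(qa)) {
    ep <- eta
    ep[, ai[k]] <- ep[, ai[k]] + h
    Jw[, k] <- -(struct_pred(prep, base, thetas, ep) - f0) / (h * sd_obs)
  }
  H11 <- arm_sum(Jw[, 1L]^2, prep) + 1 / om[ai[1L]]^2
  if (qa == 1L) return(list(H11 = H11, H22 = NULL, H12 = NULL))
  list(H11 = H11,
       H22 = arm_sum(Jw[, 2L]^2, prep) + 1 / om[ai[2L]]^2,
       H12 = arm_sum(Jw[, 1L] * Jw[, 2L], prep))
}

# Laplace-approximated -2 log marginal likelihood. `state`, when given, is
# an environment caching the previous eta modes as a warm start.
ofv_laplace <- function(phi, prep, state = NULL) {
  sp <- split_phi(phi, prep)
  eta0 <- if (!is.null(state) && !is.null(state$eta)) state$eta else NULL
  im <- tryCatch(
    inner_modes(prep, sp$base, sp$thetas, sp$om, sp$eps, eta0),
    error = function(e) NULL)
  if (is.null(im)) return(1e10)
  if (!is.null(state)) state$eta <- im$eta
  qa <- sum(im$act)
  if (qa == 0L) {
    ofv <- 2 * sum(im$qv)
  } else {
    hs <- arm_hessians(prep, sp$base, sp$thetas, sp$om, sp$eps,
                       im$eta, im$act)
    if (any(!is.finite(hs$logdet))) return(1e10)
    ofv <- sum(2 * im$qv + hs$logdet - qa * log(2 * pi))
  }
  if (!is.finite(ofv)) 1e10 else ofv
}

# --- adaptive Gauss-Hermite cross-check -------------------------------

# Hermite nodes/weights for weight exp(-x^2), via the Golub-Welsch
# tridiagonal eigenproblem.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1L)
  J <- diag(0, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- sqrt(pi) * e$vectors[1L, ]^2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

# -2 log marginal likelihood by adaptive Gauss-Hermite quadrature
# (nodes^q points per arm). Used as a numerical oracle for the Laplace
# approximation on small corpora; O(n_arms * nodes^q) structural
# evaluations per call.
ofv_agq <- function(phi, prep, nodes = 5L) {
  sp <- split_phi(phi, prep)
  im <- inner_modes(prep, sp$base, sp$thetas, sp$om, sp$eps)
  act <- im$act
  qa <- sum(act)
  if (qa == 0L) return(2 * sum(im$qv))
  hs <- arm_hessians(prep, sp$base, sp$thetas, sp$om, sp$eps, im$eta, act)
  gh <- gauss_hermite(nodes)
  if (qa == 1L) {
    grid <- matrix(gh$x, ncol = 1L)
    wts <- gh$w
  } else {
    grid <- as.matrix(expand.grid(gh$x, gh$x))
    wts <- as.vector(outer(gh$w, gh$w))
  }
  ai <- which(act)
  ll <- 0
  for (i in seq_len(prep$n_arms)) {
    Hi <- if (qa == 1L) matrix(hs$H11[i], 1L, 1L)
    else matrix(c(hs$H11[i], hs$H12[i], hs$H12[i], hs$H22[i]), 2L, 2L)
    L <- t(chol(solve(Hi)))  # lower triangular
    logq <- numeric(nrow(grid))
    for (m in seq_len(nrow(grid))) {
      eta_m <- im$eta
      eta_m[i, ai] <- im$eta[i, ai] + sqrt(2) * drop(L %*% grid[m, ])
      logq[m] <- pen_obj_arms(prep, sp$base, sp$thetas, sp$om, sp$eps,
                              eta_m, act)[i]
    }
    expo <- rowSums(grid^2) - logq
    mx <- max(expo)
    li <- 0.5 * qa * log(2) + sum(log(diag(L))) +
      mx + log(sum(wts * exp(expo - mx)))
    ll <- ll + li
  }
  -2 * ll
}
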