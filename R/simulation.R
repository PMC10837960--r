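# Estimation-scale representation (and SEs) of a parameter object or
# fit, used for Monte-Carlo parameter-uncertainty draws. Positive
# parameters live on the log scale, where an RSE is approximately the SD
# of the log.
uncertainty_spec <- function(x) {
  if (inherits(x, "mbma_fit")) {
    se <- unname(x$se_phi)
    if (all(is.na(se))) stop("fit has no standard errors")
    se[is.na(se)] <- 0
    return(list(phi = unname(x$phi), se = se, prep = x$prep,
                params = x$params,
                endpoint = x$endpoint))
  }
  if (inherits(x, "os_params")) {
    nmb <- names(x$base)
    phi <- c(log(x$base), x$thetas, log(pmax(x$eta_sd, 1e-12)),
             log(max(x$eps_sd, 1e-12)))
    nms <- c(nmb, if (length(x$thetas)) paste0("theta_", names(x$thetas)),
             paste0("eta_sd_", nmb), "eps_sd")
  } else if (inherits(x, "emax_params")) {
    phi <- c(log(x$base), log(pmax(x$eta_sd, 1e-12)),
             log(max(x$eps_sd, 1e-12)))
    nms <- c(names(x$base), paste0("eta_sd_", c("emax", "gamma")), "eps_sd")
  } else stop("x must be a fit or a parameter object")
  se <- rep(0, length(phi))
  names(phi) <- nms
  if (!is.null(x$rse_pct)) {
    for (nm in names(x$rse_pct)) {
      j <- match(nm, nms)
      if (is.na(j) && inherits(x, "os_params")) {
        jj <- match(paste0("theta_", sub("^theta_duration$", "duration_months",
                                         sub("^theta_riluzole$",
                                             "riluzole_frac", nm))), nms)
        j <- jj
      }
      if (is.na(j)) next
      if (grepl("^theta_", nms[j]))
        se[j] <- abs(phi[j]) * x$rse_pct[[nm]] / 100
      else se[j] <- x$rse_pct[[nm]] / 100
    }
  }
  list(phi = unname(phi), se = se, nms = nms, params = x,
       endpoint = if (inherits(x, "os_params")) "OS" else "ALSFRS")
}

params_from_phi_draw <- function(spec, phi_d) {
  p0 <- spec$params
  if (spec$endpoint == "OS") {
    nb <- length(p0$base)
    nt <- length(p0$thetas)
    base <- stats::setNames(exp(phi_d[seq_len(nb)]), names(p0$base))
    thetas <- if (nt) stats::setNames(phi_d[nb + seq_len(nt)],
                                      names(p0$thetas)) else numeric(0)
    os_params_general(p0$hazard, base, thetas = thetas,
                      centers = p0$centers,
                      eta_sd = stats::setNames(exp(phi_d[nb + nt +
                                                           seq_len(nb)]),
                                               names(p0$base)),
                      eps_sd = exp(phi_d[length(phi_d)]),
                      obs_scale = p0$obs_scale)
  } else {
    b <- exp(phi_d[1:3])
    emax_params(emax = min(b[1L], 48), et50 = b[2L], gamma = b[3L],
                eta_sd_emax = exp(phi_d[4L]), eta_sd_gamma = exp(phi_d[5L]),
                eps_sd = exp(phi_d[6L]))
  }
}

fit_phi_to_spec_phi <- function(spec) {
  # an mbma_fit's phi already has the right layout
  spec
}

#' Monte-Carlo simulation of the typical disease course
#'
#' Propagates parameter uncertainty through the fitted (or published)
#' model: parameter vectors are drawn as independent normals on the
#' estimation scale (log scale for positive parameters, so an RSE maps
#' to the SD of the log), the deterministic course is computed per draw,
#' and pointwise medians with 2.5th/97.5th percentile bounds are
#' returned. The summary holds the median OS (OS endpoint) or the
#' typical changes at 12/24/48 months (ALSFRS endpoint), each with its
#' 95% interval. With `include_eta = TRUE` a study-level random effect
#' is additionally drawn per replicate, widening the band from the
#' typical-study course to the between-study distribution. With
#' `draws = "bootstrap"` parameter vectors are resampled from stored
#' bootstrap replicates instead of the normal approximation.
#'
#' @param x A converged `mbma_fit`, or an [os_params()] /
#'   [emax_params()] object carrying `rse_pct` (e.g.
#'   [als_reference_params()]).
#' @param cov A [covariate_profile()] (required for OS).
#' @param times Time grid in months (default 0--60 for OS, 0--48 for
#'   ALSFRS, monthly).
#' @param n_mc Number of Monte-Carlo draws (default 1000).
#' @param seed Optional seed.
#' @param include_eta Draw study random effects as well (default FALSE:
#'   the population-typical study).
#' @param draws `"normal"` (independent normals on the estimation
#'   scale) or `"bootstrap"` (resample `boot$replicates`).
#' @param boot An `mbma_bootstrap` object when `draws = "bootstrap"`.
#' @return An object of class `typical_course` with elements `time`,
#'   `point` (pointwise median), `lo95`, `hi95`, `n_mc`, and `summary`.
#' @export
#' @examples
#' p <- als_reference_params("ALSFRS")
#' tc <- simulate_typical(p, n_mc = 200, seed = 1)
#' tc$summary
simulate_typical <- function(x, cov = NULL, times = NULL, n_mc = 1000L,
                             seed = NULL, include_eta = FALSE,
                             draws = c("normal", "bootstrap"), boot = NULL) {
  draws <- match.arg(draws)
  spec <- uncertainty_spec(x)
  endpoint <- spec$endpoint
  if (endpoint == "OS" && is.null(cov))
    stop("OS simulation requires a covariate profile")
  if (is.null(times))
    times <- if (endpoint == "OS") seq(0, 60, by = 1) else seq(0, 48, by = 1)
  if (!is.null(seed)) set.seed(seed)
  n_redrawn <- 0L
  draw_params <- function() {
    if (draws == "bootstrap") {
      if (is.null(boot)) stop("draws = 'bootstrap' needs a boot object")
      row <- boot$replicates[sample.int(nrow(boot$replicates), 1L), ]
      logidx <- !grepl("^theta_", colnames(boot$replicates))
      phi_d <- ifelse(logidx, log(pmax(row, 1e-12)), row)
      return(params_from_phi_draw(spec, unname(phi_d)))
    }
    for (tries in 1:100) {
      phi_d <- spec$phi + stats::rnorm(length(spec$phi), 0, spec$se)
      p <- tryCatch(params_from_phi_draw(spec, phi_d),
                    error = function(e) NULL)
      if (!is.null(p)) return(p)
      n_redrawn <<- n_redrawn + 1L
    }
    stop("could not draw valid parameters")
  }
  curves <- matrix(NA_real_, length(times), n_mc)
  summ <- if (endpoint == "OS") matrix(NA_real_, 1L, n_mc)
  else matrix(NA_real_, 3L, n_mc)
  for (m in seq_len(n_mc)) {
    p <- draw_params()
    eta <- if (include_eta)
      stats::rnorm(length(p$eta_sd), 0, p$eta_sd)
    else NULL
    if (endpoint == "OS") {
      curves[, m] <- os_survival(times, cov, p, eta)
      summ[1L, m] <- tryCatch(median_os(cov, p, eta),
                              error = function(e) NA_real_)
    } else {
      eta2 <- if (is.null(eta)) c(0, 0) else eta
      curves[, m] <- typical_change(times, p, eta2)
      summ[, m] <- typical_change(c(12, 24, 48), p, eta2)
    }
  }
  qs <- function(v) stats::quantile(v, c(0.025, 0.5, 0.975), type = 7,
                                    na.rm = TRUE)
  bands <- apply(curves, 1L, qs)
  summary_tab <- t(apply(summ, 1L, qs))
  rownames(summary_tab) <- if (endpoint == "OS") "median_os"
  else c("change_12m", "change_24m", "change_48m")
  colnames(summary_tab) <- c("lo95", "point", "hi95")
  structure(list(covariates = cov, time = times,
                 point = bands[2L, ], lo95 = bands[1L, ],
                 hi95 = bands[3L, ], n_mc = n_mc,
                 include_eta = include_eta, endpoint = endpoint,
                 n_redrawn = n_redrawn,
                 summary = summary_tab),
            class = "typical_course")
}

#' @export
print.typical_course <- function(x, ...) {
  cat(sprintf("Typical %s course (%d Monte-Carlo draws%s)\n",
              x$endpoint, x$n_mc,
              if (x$include_eta) ", between-study effects included" else ""))
  print(signif(x$summary, 4))
  invisible(x)
}

#' @export
plot.typical_course <- function(x, ...) {
  ylim <- range(x$lo95, x$hi95)
  graphics::plot(x$time, x$point, type = "l", lwd = 2,
                 xlab = "time (months)",
                 ylab = if (x$endpoint == "OS") "survival proportion"
                 else "ALSFRS-R change", ylim = ylim, ...)
  graphics::lines(x$time, x$lo95, lty = 2)
  graphics::lines(x$time, x$hi95, lty = 2)
  invisible(x)
}

#' Plug-in scenario table for the OS model
#'
#' Median OS and survival rates at landmark times for a list of
#' covariate scenarios, evaluated at the point estimates (no
#' Monte-Carlo).
#'
#' @param x A fitted OS model or an [os_params()] object.
#' @param scenarios List of [covariate_profile()] objects.
#' @param landmarks Landmark times, months (default 12, 24, 60).
#' @return A data frame: one row per scenario with the covariates, the
#'   median OS and `S(t)` at each landmark.
#' @export
scenario_table <- function(x, scenarios, landmarks = c(12, 24, 60)) {
  p <- if (inherits(x, "mbma_fit")) {
    if (x$endpoint != "OS") stop("scenario_table requires an OS model")
    x$params
  } else x
  stopifnot(inherits(p, "os_params"))
  rows <- lapply(scenarios, function(cv) {
    med <- tryCatch(median_os(cv, p), error = function(e) NA_real_)
    s <- os_survival(landmarks, cv, p)
    out <- data.frame(duration_months = cv$duration_months,
                      riluzole_frac = cv$riluzole_frac,
                      median_os = med)
    for (j in seq_along(landmarks))
      out[[sprintf("surv_%gm", landmarks[j])]] <- s[j]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
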