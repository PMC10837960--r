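#' Goodness-of-fit table
#'
#' One row per observation with the observation, population prediction
#' (PRED, random effects at zero), individual prediction (IPRED, at the
#' empirical-Bayes modes), and conditional weighted residual (CWRES).
#' CWRES standardizes the residual from the population prediction by
#' the model-implied covariance under a first-order linearization of
#' the random effects at zero: per arm,
#' `Cov = J0 diag(om^2) J0' + diag((w * eps)^2)` and the residual vector
#' is whitened with the Cholesky factor of `Cov`. Values are on the
#' observation scale used by the likelihood.
#'
#' @param fit A converged `mbma_fit`.
#' @param corpus Optional corpus (defaults to the fitted one).
#' @return A data frame of class `gof_table`: `study_id`, `time`, `obs`,
#'   `pred`, `ipred`, `cwres`.
#' @export
gof <- function(fit, corpus = NULL) {
  stopifnot(inherits(fit, "mbma_fit"))
  prep <- if (is.null(corpus)) fit$prep
  else prep_likelihood(corpus, fit$endpoint,
                       if (fit$endpoint == "OS") fit$hazard else "lognormal",
                       fit$covariates, fit$obs_scale, fit$weighting)
  sp <- split_phi(unname(fit$phi), prep)
  zero <- matrix(0, prep$n_arms, prep$q)
  pred <- struct_pred(prep, sp$base, sp$thetas, zero)
  im <- inner_modes(prep, sp$base, sp$thetas, sp$om, sp$eps)
  ipred <- struct_pred(prep, sp$base, sp$thetas, im$eta)
  # first-order Jacobian wrt eta at zero
  h <- 1e-5
  J <- matrix(0, prep$n_obs, prep$q)
  for (k in seq_len(prep$q)) {
    ek <- zero
    ek[, k] <- h
    J[, k] <- (struct_pred(prep, sp$base, sp$thetas, ek) - pred) / h
  }
  e <- prep$y - pred
  cwres <- numeric(prep$n_obs)
  for (i in seq_len(prep$n_arms)) {
    sel <- which(prep$arm == i)
    Ji <- J[sel, , drop = FALSE]
    Vi <- Ji %*% diag(sp$om^2, prep$q) %*% t(Ji) +
      diag((prep$w[sel] * sp$eps)^2, length(sel))
    L <- t(chol(Vi))
    cwres[sel] <- forwardsolve(L, e[sel])
  }
  out <- data.frame(study_id = prep$study_ids[prep$arm], time = prep$t,
                    obs = prep$y, pred = pred, ipred = ipred, cwres = cwres,
                    stringsAsFactors = FALSE)
  class(out) <- c("gof_table", "data.frame")
  out
}

#' Visual predictive check
#'
#' Simulates `n_sim` corpus replicates under the original design
#' (drawing study effects and residual noise), bins observation times
#' into quantile-based bins, and returns per-bin 2.5th/50th/97.5th
#' percentiles of the simulated observations together with the fraction
#' of real observations falling inside the 95% band. Empty bins are
#' merged with their neighbor.
#'
#' @param fit A converged `mbma_fit`.
#' @param n_sim Number of simulated replicates (default 1000).
#' @param bins Number of quantile bins on observation time (default 8).
#' @param seed Optional seed.
#' @return An object of class `mbma_vpc`: a band table (`bin_mid`,
#'   `p2.5`, `p50`, `p97.5`, `n_obs`, `frac_inside`), the overall
#'   `frac_inside`, and the observed points. Values are on the natural
#'   scale (survival proportion / score change).
#' @export
vpc <- function(fit, n_sim = 1000L, bins = 8L, seed = NULL) {
  stopifnot(inherits(fit, "mbma_fit"))
  prep <- fit$prep
  sims <- simulate_observations(fit, n_sim = n_sim, seed = seed)
  obs <- prep$y_nat
  # quantile bins on time; merge bins holding no observations
  brk <- unique(stats::quantile(prep$t, probs = seq(0, 1, length.out =
                                                      bins + 1L), type = 7))
  bin <- cut(prep$t, breaks = brk, include.lowest = TRUE)
  counts <- table(bin)
  if (any(counts == 0)) {
    message("empty time bin(s) merged with neighbor")
    bin <- droplevels(bin)
  }
  lev <- levels(bin)
  rows <- lapply(lev, function(lv) {
    sel <- bin == lv
    sim_v <- as.vector(sims[sel, , drop = FALSE])
    qs <- stats::quantile(sim_v, c(0.025, 0.5, 0.975), type = 7)
    inside <- obs[sel] >= qs[1L] & obs[sel] <= qs[3L]
    data.frame(bin = lv, bin_mid = stats::median(prep$t[sel]),
               p2.5 = qs[1L], p50 = qs[2L], p97.5 = qs[3L],
               n_obs = sum(sel), frac_inside = mean(inside),
               stringsAsFactors = FALSE)
  })
  band <- do.call(rbind, rows)
  rownames(band) <- NULL
  overall <- sum(band$frac_inside * band$n_obs) / sum(band$n_obs)
  structure(list(band = band, frac_inside = overall, n_sim = n_sim,
                 endpoint = fit$endpoint,
                 observed = data.frame(time = prep$t, value = obs)),
            class = "mbma_vpc")
}

#' @export
print.mbma_vpc <- function(x, ...) {
  cat(sprintf("Visual predictive check (%s, %d simulations)\n",
              x$endpoint, x$n_sim))
  print(transform(x$band, p2.5 = signif(p2.5, 4), p50 = signif(p50, 4),
                  p97.5 = signif(p97.5, 4),
                  frac_inside = round(frac_inside, 3)), row.names = FALSE)
  cat(sprintf("fraction of observations inside the 95%% band: %.3f\n",
              x$frac_inside))
  invisible(x)
}

#' @export
plot.mbma_vpc <- function(x, ...) {
  b <- x$band
  ylim <- range(b$p2.5, b$p97.5, x$observed$value)
  graphics::plot(x$observed$time, x$observed$value, pch = 16,
                 col = "grey40", xlab = "time (months)",
                 ylab = if (x$endpoint == "OS") "survival proportion"
                 else "ALSFRS-R change", ylim = ylim, ...)
  graphics::lines(b$bin_mid, b$p50, lwd = 2)
  graphics::lines(b$bin_mid, b$p2.5, lty = 2)
  graphics::lines(b$bin_mid, b$p97.5, lty = 2)
  invisible(x)
}

#' Write VPC band data as TSV
#'
#' @param x An `mbma_vpc` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vpc <- function(x, path) {
  stopifnot(inherits(x, "mbma_vpc"))
  utils::write.table(x$band[, c("bin_mid", "p2.5", "p50", "p97.5", "n_obs",
                                "frac_inside")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
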