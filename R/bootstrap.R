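#' Nonparametric bootstrap of the final model
#'
#' Resamples arms (study level) with replacement and refits the model
#' per replicate, warm-started from the point estimates with a single
#' optimization start. A replicate counts as successful when the
#' optimizer converges with finite estimates, finite objective and a
#' finite diagonal of the outer Hessian; failures are counted and
#' excluded. Identical resamples (which arise in tiny corpora) are
#' fitted once and reused.
#'
#' @param fit A converged `mbma_fit`.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Optional seed for resampling.
#' @param ... Further arguments to [mbma_fit()].
#' @return An object of class `mbma_bootstrap`: `n_attempted`,
#'   `n_success`, per-parameter `median` and `ci95` (2.5th/97.5th
#'   percentiles), and the replicate estimate matrix.
#' @export
mbma_bootstrap <- function(fit, n_reps = 1000L, seed = NULL, ...) {
  stopifnot(inherits(fit, "mbma_fit"))
  if (!fit$converged) stop("bootstrap requires a converged base fit")
  if (!is.null(seed)) set.seed(seed)
  corpus <- fit$corpus
  prep0 <- fit$prep
  # only arms carrying this endpoint are resampled
  arms <- prep0$arms
  k <- length(arms)
  nm <- names(fit$phi)
  reps <- matrix(NA_real_, n_reps, length(nm),
                 dimnames = list(NULL, nm))
  ok <- logical(n_reps)
  cache <- new.env(parent = emptyenv())
  for (r in seq_len(n_reps)) {
    idx <- sort(sample.int(k, k, replace = TRUE))
    key <- paste(idx, collapse = ",")
    if (!is.null(cache[[key]])) {
      res <- cache[[key]]
    } else {
      boot_arms <- lapply(seq_along(idx), function(j) {
        a <- arms[[idx[j]]]
        a$study_id <- sprintf("%s.b%d", a$study_id, j)
        a
      })
      bc <- als_corpus(boot_arms)
      f <- tryCatch(
        mbma_fit(bc, fit$endpoint,
                 base_hazard = if (fit$endpoint == "OS") fit$hazard
                 else "lognormal",
                 covariates = fit$covariates, obs_scale = fit$obs_scale,
                 start = unname(fit$phi), n_starts = 1L,
                 compute_se = FALSE, weighting = fit$weighting,
                 min_arms = 1L, ...),
        error = function(e) NULL)
      res <- list(ok = FALSE, est = rep(NA_real_, length(nm)))
      if (!is.null(f) && f$converged && all(is.finite(f$estimates$estimate))
          && is.finite(f$ofv)) {
        hd <- hessian_diag_ok(f)
        if (hd) res <- list(ok = TRUE, est = f$estimates$estimate)
      }
      cache[[key]] <- res
    }
    ok[r] <- res$ok
    reps[r, ] <- res$est
  }
  n_success <- sum(ok)
  if (n_success < n_reps / 2)
    stop(sprintf(paste0("bootstrap aborted: only %d of %d replicates ",
                        "succeeded"), n_success, n_reps))
  est_ok <- reps[ok, , drop = FALSE]
  med <- apply(est_ok, 2L, stats::median)
  ci <- apply(est_ok, 2L, stats::quantile, probs = c(0.025, 0.975),
              type = 7)
  structure(list(n_attempted = n_reps, n_success = n_success,
                 median = med,
                 ci95 = t(ci), replicates = est_ok,
                 point = stats::setNames(fit$estimates$estimate, nm)),
            class = "mbma_bootstrap")
}

# cheap finiteness check of the outer Hessian diagonal at the replicate
# solution (central differences, 2 evaluations per parameter)
hessian_diag_ok <- function(fit, h = 1e-4) {
  prep <- fit$prep
  phi <- unname(fit$phi)
  state <- new.env(parent = emptyenv())
  f0 <- ofv_laplace(phi, prep, state)
  for (j in seq_along(phi)) {
    pp <- phi; pp[j] <- pp[j] + h
    pm <- phi; pm[j] <- pm[j] - h
    d2 <- (ofv_laplace(pp, prep, state) - 2 * f0 +
             ofv_laplace(pm, prep, state)) / h^2
    if (!is.finite(d2)) return(FALSE)
  }
  TRUE
}

#' @export
print.mbma_bootstrap <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap: %d of %d replicates successful\n",
              x$n_success, x$n_attempted))
  tab <- data.frame(parameter = names(x$median),
                    point = signif(unname(x$point), 4),
                    median = signif(unname(x$median), 4),
                    lo95 = signif(x$ci95[, 1L], 4),
                    hi95 = signif(x$ci95[, 2L], 4))
  print(tab, row.names = FALSE)
  invisible(x)
}
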