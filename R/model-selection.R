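#' Rank candidate base hazards for the OS model
#'
#' Fits each candidate base survival family with identical settings
#' (same covariates, scale and optimizer control) and ranks the
#' converged fits by AIC (`OFV + 2 * n_par`); ties are broken in favor
#' of fewer parameters. Non-convergent candidates are excluded with a
#' message.
#'
#' @param corpus An [als_corpus()] with OS data.
#' @param candidates Character vector of base families to try.
#' @param covariates Covariate specification passed to [mbma_fit()];
#'   default none (base-model comparison precedes covariate modeling).
#' @param ... Further arguments to [mbma_fit()] (e.g. `n_starts`).
#' @return An object of class `hazard_selection`: a ranked table plus
#'   the underlying fits.
#' @export
select_base_hazard <- function(corpus,
                               candidates = c("lognormal", "weibull",
                                              "loglogistic", "exponential"),
                               covariates = list(), ...) {
  fits <- list()
  rows <- list()
  for (h in candidates) {
    f <- tryCatch(mbma_fit(corpus, "OS", base_hazard = h,
                           covariates = covariates, ...),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      message("candidate ", h, " excluded: ",
              if (is.null(f)) "fit failed" else "did not converge")
      next
    }
    fits[[h]] <- f
    rows[[h]] <- data.frame(hazard = h, n_par = f$n_par, ofv = f$ofv,
                            aic = f$ofv + 2 * f$n_par,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no candidate base hazard converged")
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aic, tab$n_par), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "hazard_selection")
}

#' @export
print.hazard_selection <- function(x, ...) {
  cat("Base-hazard selection (ranked by AIC):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Stepwise covariate model building
#'
#' Forward inclusion followed by backward elimination on the
#' likelihood-ratio scale: a candidate enters when it drops the
#' objective function by more than `forward_dofv` (default 3.84,
#' p < 0.05 at 1 df) and survives elimination only if its removal
#' raises the objective by more than `backward_dofv` (default 6.63,
#' p < 0.01). Covariate effects are linear on the log hazard (OS) or on
#' a log parameter (ALSFRS); continuous covariates are centered at the
#' corpus median. Candidates nearly collinear (|r| > 0.95) with an
#' already-included covariate are skipped with a warning.
#'
#' @param corpus An [als_corpus()].
#' @param endpoint `"OS"` or `"ALSFRS"`.
#' @param candidates List of candidate effects: covariate names (OS) or
#'   `list(cov =, on =)` pairs.
#' @param forward_dofv,backward_dofv Inclusion/retention thresholds on
#'   the -2 log-likelihood drop.
#' @param ... Further arguments to [mbma_fit()].
#' @return A list of class `covariate_search`: `fit` (the final model)
#'   and `trace` (a data frame of steps: covariate, OFV, delta OFV,
#'   decision).
#' @export
covariate_search <- function(corpus, endpoint = c("OS", "ALSFRS"),
                             candidates, forward_dofv = 3.84,
                             backward_dofv = 6.63, ...) {
  endpoint <- match.arg(endpoint)
  candidates <- normalize_covariates(candidates, endpoint)
  cand_key <- vapply(candidates, function(cc) paste(cc$cov, cc$on, sep = ":"),
                     character(1))
  cur <- NULL
  fit_with <- function(included) {
    # warm-start candidate fits from the current model so OFV drops
    # reflect the covariate, not optimizer restarts
    mbma_fit(corpus, endpoint, covariates = if (length(included)) included
             else list(),
             start = if (!is.null(cur)) cur$params, ...)
  }
  cov_values <- function(cc) {
    vapply(corpus$arms, function(a) as.numeric(a$covariates[[cc$cov]]),
           numeric(1))
  }
  included <- list()
  cur <- fit_with(included)
  trace <- list(data.frame(step = "base", covariate = "(none)",
                           ofv = cur$ofv, delta_ofv = NA_real_,
                           decision = "start", stringsAsFactors = FALSE))
  remaining <- candidates
  rem_key <- cand_key
  # forward inclusion
  repeat {
    if (!length(remaining)) break
    best_i <- NA_integer_; best_dofv <- -Inf; best_fit <- NULL
    for (i in seq_along(remaining)) {
      cc <- remaining[[i]]
      if (length(included)) {
        r <- suppressWarnings(vapply(included, function(ic)
          stats::cor(cov_values(cc), cov_values(ic),
                     use = "complete.obs"), numeric(1)))
        if (any(abs(r) > 0.95, na.rm = TRUE)) {
          warning("candidate ", cc$cov, " collinear with included ",
                  "covariate; skipped")
          next
        }
      }
      f <- tryCatch(fit_with(c(included, list(cc))),
                    error = function(e) NULL)
      if (is.null(f)) next
      dofv <- cur$ofv - f$ofv
      trace[[length(trace) + 1L]] <-
        data.frame(step = "forward", covariate = rem_key[i], ofv = f$ofv,
                   delta_ofv = dofv,
                   decision = if (dofv > forward_dofv) "candidate"
                   else "rejected", stringsAsFactors = FALSE)
      if (dofv > best_dofv) {
        best_dofv <- dofv; best_i <- i; best_fit <- f
      }
    }
    if (!is.na(best_i) && best_dofv > forward_dofv) {
      included <- c(included, remaining[best_i])
      trace[[length(trace) + 1L]] <-
        data.frame(step = "forward", covariate = rem_key[best_i],
                   ofv = best_fit$ofv, delta_ofv = best_dofv,
                   decision = "included", stringsAsFactors = FALSE)
      cur <- best_fit
      remaining <- remaining[-best_i]
      rem_key <- rem_key[-best_i]
    } else break
  }
  # backward elimination
  repeat {
    if (!length(included)) break
    removed <- FALSE
    dofvs <- numeric(length(included))
    fits <- vector("list", length(included))
    for (i in seq_along(included)) {
      f <- tryCatch(fit_with(included[-i]), error = function(e) NULL)
      fits[[i]] <- f
      dofvs[i] <- if (is.null(f)) Inf else f$ofv - cur$ofv
    }
    i <- which.min(dofvs)
    key_i <- paste(included[[i]]$cov, included[[i]]$on, sep = ":")
    if (dofvs[i] <= backward_dofv) {
      trace[[length(trace) + 1L]] <-
        data.frame(step = "backward", covariate = key_i,
                   ofv = fits[[i]]$ofv, delta_ofv = dofvs[i],
                   decision = "removed", stringsAsFactors = FALSE)
      cur <- fits[[i]]
      included <- included[-i]
      removed <- TRUE
    } else {
      trace[[length(trace) + 1L]] <-
        data.frame(step = "backward", covariate = key_i, ofv = cur$ofv,
                   delta_ofv = dofvs[i], decision = "retained",
                   stringsAsFactors = FALSE)
    }
    if (!removed) break
  }
  structure(list(fit = cur, included = included,
                 trace = do.call(rbind, trace)),
            class = "covariate_search")
}

#' @export
print.covariate_search <- function(x, ...) {
  cat("Stepwise covariate search\n")
  inc <- vapply(x$included, function(cc) paste(cc$cov, cc$on, sep = ":"),
                character(1))
  cat("  final model covariates:",
      if (length(inc)) paste(inc, collapse = ", ") else "(none)", "\n")
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Write a covariate-search trace as TSV
#'
#' @param x A `covariate_search` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "covariate_search"))
  utils::write.table(x$trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
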