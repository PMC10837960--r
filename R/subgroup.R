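#' Random-effects meta-analytic pooling (DerSimonian-Laird)
#'
#' Pools per-study estimates with the DerSimonian-Laird moment
#' estimator: with fixed-effect weights `w = 1/se^2`,
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`, the pooled
#' mean uses weights `w* = 1/(se^2 + tau2)` and the pooled SE is
#' `1/sqrt(sum(w*))`. With `tau2 = 0` this reduces to inverse-variance
#' fixed-effect pooling.
#'
#' @param estimates Per-study estimates.
#' @param ses Per-study standard errors (positive).
#' @return A list: `mean`, `se`, `tau2`, `k`, `Q`.
#' @export
#' @examples
#' pool_random_effects(c(1, 2, 3), c(1, 1, 1))  # mean 2, se 1/sqrt(3)
pool_random_effects <- function(estimates, ses) {
  k <- length(estimates)
  if (k == 0L) stop("at least one study is required")
  stopifnot(length(ses) == k, all(ses > 0))
  w <- 1 / ses^2
  xbar <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - xbar)^2)
  tau2 <- if (k == 1L) 0 else
    max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wstar <- 1 / (ses^2 + tau2)
  list(mean = sum(wstar * estimates) / sum(wstar),
       se = 1 / sqrt(sum(wstar)), tau2 = tau2, k = k, Q = Q)
}

#' Define a subgroup split
#'
#' Continuous covariates are split at the corpus median (recomputed from
#' the data at analysis time); `pub_year` splits at 2009 by default;
#' `basic_treatment` splits on the flag. Arms missing the covariate are
#' excluded from that split.
#'
#' @param variable Covariate name (a field of [covariate_profile()]).
#' @param cutpoint Optional numeric cutpoint overriding the default
#'   rule.
#' @return An object of class `subgroup_spec`.
#' @export
subgroup_spec <- function(variable, cutpoint = NULL) {
  structure(list(variable = variable, cutpoint = cutpoint),
            class = "subgroup_spec")
}

assign_subgroup <- function(spec, arms) {
  x <- vapply(arms, function(a) as.numeric(a$covariates[[spec$variable]]),
              numeric(1))
  cut <- spec$cutpoint
  if (spec$variable == "basic_treatment") {
    lev <- ifelse(is.na(x), NA, ifelse(x > 0, "yes", "no"))
    return(list(level = lev, cutpoint = NA_real_))
  }
  if (is.null(cut))
    cut <- if (spec$variable == "pub_year") 2009
  else stats::median(x, na.rm = TRUE)
  lev <- ifelse(is.na(x), NA,
                ifelse(x > cut, sprintf("> %g", cut), sprintf("<= %g", cut)))
  list(level = lev, cutpoint = cut)
}

#' Subgroup analysis of the fitted disease-course model
#'
#' Two-stage subgroup analysis: (1) empirical-Bayes study-level
#' parameters (covariate effects removed, i.e. at the reference
#' profile) are pooled per subgroup with a random-effects meta-analysis
#' on the log scale; (2) the subgroup typical course summary (median OS
#' or ALSFRS-R change at a landmark) is simulated by Monte Carlo from
#' the pooled distributions. Subgroups with no arms are omitted with a
#' warning.
#'
#' @param fit A converged `mbma_fit`.
#' @param specs List of [subgroup_spec()] objects (or covariate names).
#' @param n_mc Monte-Carlo draws per subgroup (default 1000).
#' @param seed Optional seed.
#' @param reference_cov Covariate profile at which OS summaries are
#'   evaluated; defaults to corpus medians of duration and riluzole.
#' @param landmark Landmark month for the ALSFRS-R summary (default 12).
#' @return A data frame of class `subgroup_analysis`: one row per
#'   subgroup level with `k`, the pooled typical summary and its 95% CI.
#' @export
subgroup_analysis <- function(fit, specs, n_mc = 1000L, seed = NULL,
                              reference_cov = NULL, landmark = 12) {
  stopifnot(inherits(fit, "mbma_fit"))
  if (!fit$converged) stop("subgroup analysis requires a converged fit")
  if (!is.null(seed)) set.seed(seed)
  specs <- lapply(specs, function(s)
    if (inherits(s, "subgroup_spec")) s else subgroup_spec(s))
  eb <- fit$eb
  prep <- fit$prep
  arms <- prep$arms
  enames <- if (fit$endpoint == "OS") prep$base_names else c("emax", "gamma")
  if (is.null(reference_cov) && fit$endpoint == "OS") {
    dmed <- stats::median(vapply(arms, function(a)
      a$covariates$duration_months, numeric(1)))
    rmed <- stats::median(vapply(arms, function(a)
      a$covariates$riluzole_frac, numeric(1)))
    reference_cov <- covariate_profile(dmed, rmed)
  }
  p0 <- fit$params
  summarize_draw <- function(p) {
    if (fit$endpoint == "OS")
      tryCatch(median_os(reference_cov, p), error = function(e) NA_real_)
    else typical_change(landmark, p)
  }
  rows <- list()
  for (spec in specs) {
    asg <- assign_subgroup(spec, arms)
    for (lv in stats::na.omit(unique(asg$level))) {
      sel <- which(!is.na(asg$level) & asg$level == lv)
      if (!length(sel)) {
        warning("subgroup ", spec$variable, " ", lv, " has no arms; omitted")
        next
      }
      # pool each random-effect parameter on the log scale
      pooled <- lapply(enames, function(en) {
        est <- log(eb[[en]][sel])
        se <- eb[[paste0("cond_sd_", en)]][sel]
        pool_random_effects(est, pmax(se, 1e-6))
      })
      names(pooled) <- enames
      sums <- vapply(seq_len(n_mc), function(m) {
        pd <- p0
        for (en in enames) {
          v <- exp(stats::rnorm(1, pooled[[en]]$mean, pooled[[en]]$se))
          pd$base[[en]] <- v
          if (!is.null(pd[[en]])) pd[[en]] <- v
          if (en == "mu") pd$mu <- v
          if (en == "sigm") pd$sigm <- v
        }
        summarize_draw(pd)
      }, numeric(1))
      qs <- stats::quantile(sums, c(0.025, 0.5, 0.975), type = 7,
                            na.rm = TRUE)
      rows[[length(rows) + 1L]] <-
        data.frame(variable = spec$variable, level = lv, k = length(sel),
                   estimate = qs[2L], lo95 = qs[1L], hi95 = qs[3L],
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("subgroup_analysis", "data.frame")
  out
}

#' Write subgroup results as forest-plot-style TSV
#'
#' @param x A `subgroup_analysis` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subgroups <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
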