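#' Covariate profile of a trial arm
#'
#' Arm-level covariates used by the survival and functional-score models.
#' Disease duration is the time from first symptom onset to enrollment and
#' must be positive; all proportions lie in \[0, 1\]; the baseline ALSFRS-R
#' score lies on the 0--48 scale. Optional covariates may be `NA`.
#'
#' @param duration_months Positive disease duration at enrollment, months.
#' @param riluzole_frac Proportion of the arm receiving riluzole, in \[0, 1\].
#' @param age_onset_years Optional mean age at symptom onset, years.
#' @param male_frac Optional proportion of male participants.
#' @param bulbar_frac Optional proportion with bulbar onset.
#' @param baseline_alsfrs Optional mean baseline ALSFRS-R score (0--48).
#' @param basic_treatment Optional 0/1 flag for symptomatic basic treatment.
#' @param pub_year Optional publication year (integer).
#' @return An object of class `covariate_profile`.
#' @export
#' @examples
#' covariate_profile(duration_months = 17.8, riluzole_frac = 0.9)
covariate_profile <- function(duration_months, riluzole_frac,
                              age_onset_years = NA_real_,
                              male_frac = NA_real_,
                              bulbar_frac = NA_real_,
                              baseline_alsfrs = NA_real_,
                              basic_treatment = NA_real_,
                              pub_year = NA_integer_) {
  stopifnot(is.numeric(duration_months), length(duration_months) == 1L,
            is.numeric(riluzole_frac), length(riluzole_frac) == 1L)
  if (!is.finite(duration_months) || duration_months <= 0)
    stop("duration_months must be a positive number")
  chk_frac <- function(x, nm) {
    if (!is.na(x) && (x < 0 || x > 1))
      stop(sprintf("%s must lie in [0, 1]", nm))
  }
  chk_frac(riluzole_frac, "riluzole_frac")
  chk_frac(male_frac, "male_frac")
  chk_frac(bulbar_frac, "bulbar_frac")
  if (is.na(riluzole_frac)) stop("riluzole_frac is required")
  if (!is.na(baseline_alsfrs) && (baseline_alsfrs < 0 || baseline_alsfrs > 48))
    stop("baseline_alsfrs must lie in [0, 48]")
  structure(list(duration_months = as.numeric(duration_months),
                 riluzole_frac = as.numeric(riluzole_frac),
                 age_onset_years = as.numeric(age_onset_years),
                 male_frac = as.numeric(male_frac),
                 bulbar_frac = as.numeric(bulbar_frac),
                 baseline_alsfrs = as.numeric(baseline_alsfrs),
                 basic_treatment = as.numeric(basic_treatment),
                 pub_year = as.integer(pub_year)),
            class = "covariate_profile")
}

#' Construct a single aggregate placebo arm
#'
#' A study arm carries its sample size, covariates, and one or both
#' observation series: digitized Kaplan-Meier survival proportions
#' (`os_series`) and mean ALSFRS-R changes from baseline (`score_series`).
#' Times must be strictly increasing within a series; survival proportions
#' must lie in (0, 1\] and be non-increasing (zero values are rejected
#' because downstream scales take logs).
#'
#' @param study_id Unique study identifier (character).
#' @param n Arm sample size; must be at least 11 (trials with 10 or fewer
#'   subjects are outside the corpus inclusion rule).
#' @param covariates A [covariate_profile()].
#' @param os_series `NULL` or a data frame with columns `time_months`,
#'   `surv_prob`.
#' @param score_series `NULL` or a data frame with columns `time_months`,
#'   `mean_change` and optionally `se`.
#' @param strict Enforce monotone non-increasing survival (default TRUE;
#'   relaxed for raw, non-monotonized simulation noise).
#' @return An object of class `study_arm`.
#' @export
study_arm <- function(study_id, n, covariates,
                      os_series = NULL, score_series = NULL,
                      strict = TRUE) {
  stopifnot(inherits(covariates, "covariate_profile"))
  n <- as.integer(n)
  if (is.na(n) || n < 11L)
    stop("arm sample size must be an integer >= 11")
  empty_os <- data.frame(time_months = numeric(0), surv_prob = numeric(0))
  empty_sc <- data.frame(time_months = numeric(0), mean_change = numeric(0),
                         se = numeric(0))
  os_series <- if (is.null(os_series) || nrow(os_series) == 0L) empty_os else {
    os <- as.data.frame(os_series)[, c("time_months", "surv_prob")]
    if (any(os$time_months < 0)) stop("OS times must be nonnegative")
    if (any(diff(os$time_months) <= 0))
      stop(sprintf("study %s: OS times must be strictly increasing", study_id))
    bad <- which(os$surv_prob <= 0 | os$surv_prob > 1)
    if (length(bad))
      stop(sprintf("study %s: surv_prob outside (0, 1] at row %d",
                   study_id, bad[1L]))
    if (strict && any(diff(os$surv_prob) > 1e-12))
      stop(sprintf("study %s: surv_prob must be non-increasing in time",
                   study_id))
    os
  }
  score_series <- if (is.null(score_series) || nrow(score_series) == 0L)
    empty_sc
  else {
    sc <- as.data.frame(score_series)
    if (is.null(sc$se)) sc$se <- NA_real_
    sc <- sc[, c("time_months", "mean_change", "se")]
    if (any(sc$time_months <= 0)) stop("score times must be positive")
    if (any(diff(sc$time_months) <= 0))
      stop(sprintf("study %s: score times must be strictly increasing",
                   study_id))
    if (any(abs(sc$mean_change) > 48))
      stop(sprintf("study %s: |mean_change| cannot exceed 48", study_id))
    if (any(!is.na(sc$se) & sc$se <= 0))
      stop(sprintf("study %s: se must be positive when given", study_id))
    sc
  }
  if (nrow(os_series) == 0L && nrow(score_series) == 0L)
    stop(sprintf("study %s: at least one observation series is required",
                 study_id))
  structure(list(study_id = as.character(study_id), n = n,
                 covariates = covariates,
                 os_series = os_series, score_series = score_series),
            class = "study_arm")
}

#' Corpus of aggregate placebo arms
#'
#' @param arms List of [study_arm()] objects with unique `study_id`s.
#' @return An object of class `als_corpus`.
#' @export
als_corpus <- function(arms) {
  stopifnot(is.list(arms), length(arms) > 0L)
  ok <- vapply(arms, inherits, logical(1), "study_arm")
  if (!all(ok)) stop("all elements must be study_arm objects")
  ids <- vapply(arms, `[[`, character(1), "study_id")
  if (anyDuplicated(ids)) stop("study_id must be unique across arms")
  structure(list(arms = arms), class = "als_corpus")
}

#' @export
print.als_corpus <- function(x, ...) {
  n_os <- sum(vapply(x$arms, function(a) nrow(a$os_series) > 0, logical(1)))
  n_sc <- sum(vapply(x$arms, function(a) nrow(a$score_series) > 0, logical(1)))
  cat(sprintf("ALS placebo corpus: %d arms (%d with OS, %d with ALSFRS-R)\n",
              length(x$arms), n_os, n_sc))
  invisible(x)
}

#' @export
length.als_corpus <- function(x) length(x$arms)

cov_fields <- c("duration_months", "riluzole_frac", "age_onset_years",
                "male_frac", "bulbar_frac", "baseline_alsfrs",
                "basic_treatment", "pub_year")

#' Flatten a corpus to the long observation table
#'
#' One row per observation with endpoint label `OS` or `ALSFRS`, the same
#' dialect [read_corpus()] consumes.
#'
#' @param x An `als_corpus`.
#' @param row.names,optional,... Passed through for S3 compatibility; unused.
#' @return A data frame.
#' @export
as.data.frame.als_corpus <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  rows <- lapply(x$arms, function(a) {
    cv <- unclass(a$covariates)
    base <- data.frame(study_id = a$study_id, n = a$n,
                       stringsAsFactors = FALSE)
    for (f in cov_fields) base[[f]] <- as.numeric(cv[[f]])
    out <- list()
    if (nrow(a$os_series)) {
      os <- data.frame(base[rep(1L, nrow(a$os_series)), , drop = FALSE],
                       endpoint = "OS",
                       time_months = a$os_series$time_months,
                       value = a$os_series$surv_prob, se = NA_real_)
      out <- c(out, list(os))
    }
    if (nrow(a$score_series)) {
      sc <- data.frame(base[rep(1L, nrow(a$score_series)), , drop = FALSE],
                       endpoint = "ALSFRS",
                       time_months = a$score_series$time_months,
                       value = a$score_series$mean_change,
                       se = a$score_series$se)
      out <- c(out, list(sc))
    }
    do.call(rbind, out)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df[, c("study_id", "n", "endpoint", "time_months", "value", "se",
         cov_fields)]
}

#' Read an aggregate-arm corpus from long CSV
#'
#' Expects one row per observation with columns `study_id`, `n`,
#' `endpoint` (`OS` or `ALSFRS`), `time_months`, `value`, optional `se`,
#' and the covariate columns `duration_months`, `riluzole_frac`,
#' `age_onset_years`, `male_frac`, `bulbar_frac`, `baseline_alsfrs`,
#' `basic_treatment`, `pub_year`. Rows with endpoint `OS` populate the
#' arm's survival series (`value` = survival proportion); rows with
#' endpoint `ALSFRS` populate the score series (`value` = mean ALSFRS-R
#' change from baseline).
#'
#' @param path Path to a UTF-8 CSV file with "." as decimal separator.
#' @return A validated [als_corpus()].
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("study_id", "n", "endpoint", "time_months", "value",
                "duration_months", "riluzole_frac")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  for (f in setdiff(cov_fields, names(df))) df[[f]] <- NA_real_
  if (is.null(df$se)) df$se <- NA_real_
  bad <- which(df$endpoint == "OS" & (df$value <= 0 | df$value > 1))
  if (length(bad))
    stop(sprintf("validation error: surv_prob outside (0, 1] in row %d",
                 bad[1L]))
  arms <- lapply(split(df, df$study_id), function(d) {
    cv <- do.call(covariate_profile, as.list(d[1L, cov_fields]))
    os <- d[d$endpoint == "OS", , drop = FALSE]
    sc <- d[d$endpoint == "ALSFRS", , drop = FALSE]
    os <- os[order(os$time_months), , drop = FALSE]
    sc <- sc[order(sc$time_months), , drop = FALSE]
    study_arm(
      study_id = d$study_id[1L], n = d$n[1L], covariates = cv,
      os_series = if (nrow(os))
        data.frame(time_months = os$time_months, surv_prob = os$value),
      score_series = if (nrow(sc))
        data.frame(time_months = sc$time_months, mean_change = sc$value,
                   se = sc$se))
  })
  arms <- arms[order(vapply(arms, `[[`, character(1), "study_id"))]
  als_corpus(unname(arms))
}

#' Write a corpus to long CSV
#'
#' Inverse of [read_corpus()]: numeric fields survive a round trip to at
#' least 10 significant digits.
#'
#' @param corpus An `als_corpus`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "als_corpus"))
  utils::write.csv(as.data.frame(corpus), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Summarize corpus characteristics as median (min-max)
#'
#' Reproduces the usual corpus-description table: per characteristic the
#' median, minimum and maximum over arms, split by which endpoint an arm
#' reports (OS, ALSFRS, and all arms). Covariates missing in every arm of
#' a group are reported `NA`.
#'
#' @param corpus An `als_corpus`.
#' @return A data frame with columns `characteristic`, `group`, `k`
#'   (number of arms with the value), `median`, `min`, `max`, and
#'   `formatted` ("median (min-max)").
#' @export
summarize_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "als_corpus"), length(corpus$arms) > 0L)
  vals <- function(arms, field) {
    if (field == "n") vapply(arms, `[[`, numeric(1), "n")
    else vapply(arms, function(a) as.numeric(a$covariates[[field]]),
                numeric(1))
  }
  has_os <- vapply(corpus$arms, function(a) nrow(a$os_series) > 0, logical(1))
  has_sc <- vapply(corpus$arms, function(a) nrow(a$score_series) > 0,
                   logical(1))
  groups <- list(OS = corpus$arms[has_os], ALSFRS = corpus$arms[has_sc],
                 ALL = corpus$arms)
  chars <- c("n", cov_fields)
  fmt1 <- function(v) {
    if (abs(v - round(v)) < 1e-9) format(round(v), scientific = FALSE)
    else format(round(v, 2), scientific = FALSE)
  }
  rows <- list()
  for (g in names(groups)) {
    arms <- groups[[g]]
    for (ch in chars) {
      v <- if (length(arms)) vals(arms, ch) else numeric(0)
      v <- v[!is.na(v)]
      if (length(v)) {
        md <- stats::median(v); mn <- min(v); mx <- max(v)
        f <- sprintf("%s (%s–%s)", fmt1(md), fmt1(mn), fmt1(mx))
      } else {
        md <- mn <- mx <- NA_real_; f <- NA_character_
      }
      rows[[length(rows) + 1L]] <-
        data.frame(characteristic = ch, group = g, k = length(v),
                   median = md, min = mn, max = mx, formatted = f,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
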